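# Shared synthetic cohorts, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small general-purpose cohort
small_cohort <- function() {
  cached("small", generate_cohort(
    generator_config(n_patients = 30, duration_min = 1440, seed = 7)))
}

small_products <- function() {
  cached("small_products", {
    ch <- small_cohort()
    flt <- apply_noise_filter(ch$vitals)
    bl <- establish_baselines(flt$vitals)
    ft <- build_feature_table(flt$vitals, bl, ch$assessments, ch$demographics)
    list(cohort = ch, filtered = flt$vitals, exclusions = flt$log,
         baselines = bl, features = ft$features, drops = ft$drops)
  })
}

# 200-patient default-condition cohort (baseline recovery, calibration,
# filter cross-checks)
cohort200 <- function() {
  cached("c200", generate_cohort(generator_config(n_patients = 200, seed = 11)))
}

cohort200_products <- function() {
  cached("c200_products", {
    ch <- cohort200()
    flt <- apply_noise_filter(ch$vitals)
    bl <- establish_baselines(flt$vitals)
    list(cohort = ch, filtered = flt$vitals, exclusions = flt$log,
         baselines = bl)
  })
}

# 500-patient cohorts for end-to-end signal detection
strong500_features <- function() {
  cached("strong500", {
    ch <- generate_cohort(generator_config(n_patients = 500, seed = 23))
    flt <- apply_noise_filter(ch$vitals)
    bl <- establish_baselines(flt$vitals)
    build_feature_table(flt$vitals, bl, ch$assessments, ch$demographics)$features
  })
}

null500_features <- function() {
  cached("null500", {
    ch <- generate_cohort(generator_config(
      n_patients = 500, seed = 23,
      pain_effect = c(hr = 0, sbp = 0, dbp = 0, rr = 0, spo2 = 0)))
    flt <- apply_noise_filter(ch$vitals)
    bl <- establish_baselines(flt$vitals)
    build_feature_table(flt$vitals, bl, ch$assessments, ch$demographics)$features
  })
}

# treatment-response cohort: pain-rich population in which every positive
# assessment triggers a bolus (emulating a dedicated fentanyl test set)
response_config <- function(n_patients, seed, duration_min = 2880,
                            responders = 0.3) {
  generator_config(n_patients = n_patients, duration_min = duration_min,
                   seed = seed, pain_episode_rate = 0.05,
                   target_positive_rate = 0.12,
                   bolus_at_positive_prob = 1,
                   bolus_response_prob = responders)
}

# feature table with gaussian deviation features for model-level unit tests
# (bypasses the generator; minority class shifted by `shift` in every
# continuous feature)
toy_features <- function(n = 600, pos_frac = 0.033, shift = 2, seed = 1) {
  set.seed(seed)
  fn <- painindex:::feature_names()
  n_pos <- max(2, round(n * pos_frac))
  lab <- factor(c(rep("negative", n - n_pos), rep("positive", n_pos)),
                levels = c("negative", "positive"))
  X <- matrix(stats::rnorm(n * length(fn)), n, length(fn),
              dimnames = list(NULL, fn))
  X[lab == "positive", ] <- X[lab == "positive", ] + shift
  df <- as.data.frame(X)
  df$patient_id <- sprintf("P%03d", sample(rep_len(1:40, n)))
  df$t_min <- seq_len(n)
  df$sex <- sample(c("male", "female"), n, replace = TRUE)
  df$age_group <- sample(c("20-44", "45-64", "65+"), n, replace = TRUE)
  df$rass <- sample(-3:1, n, replace = TRUE)
  df$label <- lab
  df
}
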