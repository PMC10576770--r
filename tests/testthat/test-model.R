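test_that("ADASYN approximately balances a rare positive class", {
  ft <- toy_features(n = 900, pos_frac = 0.033, seed = 2)
  ov <- oversample_positives(ft, ft$label, seed = 3)
  frac <- mean(ov$labels == "positive")
  expect_gte(frac, 0.4)
  expect_lte(frac, 0.6)
  # originals preserved verbatim, synthetics appended and flagged
  expect_identical(ov$features[seq_len(nrow(ft)), names(ft)], ft)
  expect_equal(sum(ov$synthetic), nrow(ov$features) - nrow(ft))
})

test_that("an already balanced input is left essentially unchanged", {
  ft <- toy_features(n = 200, pos_frac = 0.5, seed = 4)
  ov <- oversample_positives(ft, ft$label, seed = 5)
  expect_lte(nrow(ov$features), nrow(ft) * 1.05)
})

test_that("every synthetic point lies on a segment between minority neighbors", {
  ft <- toy_features(n = 400, pos_frac = 0.08, seed = 6)
  ov <- oversample_positives(ft, ft$label, seed = 7)
  cont <- painindex:::continuous_feature_cols()
  X <- as.matrix(ft[, cont])
  S <- as.matrix(ov$features[ov$synthetic, cont])
  pv <- ov$provenance
  expect_equal(nrow(S), nrow(pv))
  for (j in seq_len(nrow(S))) {
    a <- X[pv$seed_row[j], ]; b <- X[pv$partner_row[j], ]
    # both endpoints are real positives
    expect_true(all(ft$label[c(pv$seed_row[j], pv$partner_row[j])] == "positive"))
    # the point is a + lambda (b - a) with a consistent lambda in [0, 1]
    num <- S[j, ] - a; den <- b - a
    lam <- num[abs(den) > 1e-12] / den[abs(den) > 1e-12]
    expect_lt(diff(range(lam)), 1e-8)
    expect_gte(min(lam), -1e-10)
    expect_lte(max(lam), 1 + 1e-10)
    # categorical fields copied from the seed point
    expect_identical(ov$features$sex[ov$synthetic][j], ft$sex[pv$seed_row[j]])
  }
})

test_that("one-class inputs cannot be balanced", {
  ft <- toy_features(n = 100, pos_frac = 0.5, seed = 8)
  all_neg <- factor(rep("negative", 100), levels = c("negative", "positive"))
  expect_error(oversample_positives(ft, all_neg, 1), "one-class")
})

test_that("the grid search selects the single-cell operating point and fits", {
  ft <- toy_features(n = 300, pos_frac = 0.15, shift = 3, seed = 9)
  m <- grid_search_train(ft, model_config(n_estimators = 17, max_depth = 14,
                                          seed = 11))
  expect_s3_class(m, "pain_model")
  expect_equal(m$n_estimators, 17L)
  expect_equal(m$max_depth, 14L)
  # perfectly separable features give training AUROC 1
  sep <- ft
  sep$hr_dev <- ifelse(sep$label == "positive", 50, -50)
  m2 <- grid_search_train(sep, model_config(n_estimators = c(5, 17),
                                            max_depth = c(6, 14), seed = 11,
                                            inner_folds = 2))
  expect_equal(roc_auc(predict_pain_index(m2, sep), sep$label), 1.0)
})

test_that("predictions are probabilities and schema mismatches are rejected", {
  ft <- toy_features(n = 300, pos_frac = 0.15, seed = 10)
  m <- grid_search_train(ft, model_config(seed = 12))
  p <- predict_pain_index(m, ft)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_pain_index(m, ft[, -1]), "schema mismatch")
})

test_that("repeated CV is deterministic and never scores synthetic rows", {
  ft <- toy_features(n = 400, pos_frac = 0.1, seed = 13)
  cfg <- model_config(cv_folds = 4, cv_repeats = 2, seed = 14)
  a <- repeated_cv_auroc(ft, cfg)
  b <- repeated_cv_auroc(ft, cfg)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_true(a$leakage_checked)
  expect_length(a$per_repeat, 2)
  expect_false(is.na(a$sd))
  # single repeat reports sd as absent
  one <- repeated_cv_auroc(ft, model_config(cv_folds = 4, cv_repeats = 1,
                                            seed = 14))
  expect_true(is.na(one$sd))
})

test_that("label permutation destroys discrimination", {
  ft <- toy_features(n = 600, pos_frac = 0.15, shift = 3, seed = 44)
  set.seed(45)
  ft$label <- sample(ft$label)
  cv <- repeated_cv_auroc(ft, model_config(cv_folds = 3, cv_repeats = 2,
                                           seed = 45))
  expect_gt(cv$mean, 0.4)
  expect_lt(cv$mean, 0.6)
})

test_that("a stronger injected pain effect never degrades discrimination", {
  auc_for <- function(seed, scale) {
    pe <- c(hr = 10, sbp = 12, dbp = 6, rr = 4, spo2 = 0) * scale
    ch <- generate_cohort(generator_config(
      n_patients = 60, duration_min = 1440, seed = seed,
      pain_episode_rate = 0.04, pain_effect = pe))
    flt <- apply_noise_filter(ch$vitals)
    bl <- establish_baselines(flt$vitals)
    ft <- build_feature_table(flt$vitals, bl, ch$assessments,
                              ch$demographics)$features
    suppressWarnings(repeated_cv_auroc(
      ft, model_config(cv_folds = 3, cv_repeats = 1, seed = seed))$mean)
  }
  for (s in c(51, 52)) {
    expect_gte(auc_for(s, 1), auc_for(s, 0.5) - 0.05)
  }
})

test_that("the per-minute pain index respects the baseline establishment time", {
  pr <- small_products()
  ch <- pr$cohort
  m <- grid_search_train(pr$features, model_config(seed = 15))
  pid <- pr$baselines$baselines$patient_id[pr$baselines$baselines$established][1]
  b <- pr$baselines$objects[[pid]]
  ser <- pain_index_series(
    m, pr$filtered[pr$filtered$patient_id == pid, ], b,
    ch$assessments[ch$assessments$patient_id == pid, ],
    ch$demographics[ch$demographics$patient_id == pid, ],
    minutes = seq(0, b$established_at + 120))
  expect_true(all(ser$t_min >= b$established_at))
  expect_true(all(ser$pain_index >= 0 & ser$pain_index <= 1))
})

test_that("high-severity minutes score above pain-free minutes on average", {
  # pain-rich cohort so both severity strata are well populated
  ch <- cached("painrich25", generate_cohort(
    response_config(n_patients = 25, seed = 43, duration_min = 1440)))
  flt <- apply_noise_filter(ch$vitals)
  bl <- establish_baselines(flt$vitals)
  ftab <- build_feature_table(flt$vitals, bl, ch$assessments,
                              ch$demographics)$features
  pr <- list(filtered = flt$vitals, baselines = bl)
  m <- grid_search_train(ftab, model_config(seed = 16))
  hi <- c(); lo <- c()
  take <- function(x, k = 3) if (length(x))
    x[unique(round(seq(1, length(x), length.out = min(k, length(x)))))]
  else integer(0)
  for (pid in names(pr$baselines$objects)) {
    b <- pr$baselines$objects[[pid]]
    if (!b$established) next
    sev <- ch$ground_truth$severity[[pid]]
    tmax <- max(pr$filtered$t_min[pr$filtered$patient_id == pid])
    usable <- function(x) x[x >= b$established_at + 60 & x <= tmax]
    mins_hi <- take(usable(which(sev >= 1) - 1L))
    mins_lo <- take(usable(which(sev == 0) - 1L))
    if (!length(mins_hi) && !length(mins_lo)) next
    ser <- pain_index_series(
      m, pr$filtered[pr$filtered$patient_id == pid, ], b,
      ch$assessments[ch$assessments$patient_id == pid, ],
      ch$demographics[ch$demographics$patient_id == pid, ],
      minutes = sort(unique(c(mins_hi, mins_lo))))
    hi <- c(hi, ser$pain_index[ser$t_min %in% mins_hi])
    lo <- c(lo, ser$pain_index[ser$t_min %in% mins_lo])
  }
  expect_gt(length(hi), 3)
  expect_gt(length(lo), 10)
  expect_gt(mean(hi), mean(lo))
})
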