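#' @keywords internal
"_PACKAGE"

VITALS <- c("hr", "sbp", "mbp", "dbp", "rr", "spo2")
MODEL_VITALS <- c("hr", "sbp", "mbp", "dbp", "rr")

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Configuration for the synthetic ICU cohort generator
#'
#' Builds and validates the parameter set that drives [generate_cohort()].
#' Each patient receives a true per-vital baseline drawn from the population
#' means/SDs, an exponentially decaying admission-instability drift, AR(1)
#' observation noise, and latent pain episodes that additively elevate
#' HR/BP/RR through `pain_effect`. Mean arterial pressure is always derived
#' as (SBP + 2 DBP)/3 from a diastolic + pulse-pressure decomposition so the
#' ordering DBP <= MBP <= SBP holds at every uncorrupted minute.
#'
#' @param n_patients number of patients.
#' @param duration_min minutes of monitoring per patient (minute 0 =
#'   admission); must be >= 120.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   cohort byte for byte.
#' @param vitals_mean,vitals_sd population mean and between-patient SD of the
#'   true baselines, named `hr` (bpm), `sbp`, `dbp` (mmHg), `rr`
#'   (breaths/min), `spo2` (%). MBP is derived, not parameterized.
#' @param drift_magnitude admission-instability offset per vital at minute 0
#'   (same units as the vital), decaying exponentially.
#' @param drift_half_life_min half-life of the admission drift, minutes.
#' @param noise_sd marginal SD of per-minute observation noise per vital.
#' @param ar1_coefficient lag-1 autocorrelation of the observation noise,
#'   in `[0, 1)`. Default 0 (white noise): the structural components (drift,
#'   episodes) carry the temporal correlation.
#' @param pain_episode_rate onset rate of latent pain episodes per hour
#'   (Poisson; default ~0.8 per 48-h stay). Episodes ramp up over 20 min and
#'   persist until the end of monitoring unless attenuated by an analgesic
#'   response, and never start during the first 3 h after admission.
#' @param pain_effect additive shift per unit latent severity, per vital.
#' @param target_positive_rate desired fraction of CPOT assessments with
#'   CPOT >= 3; the episode severity scale is calibrated internally by
#'   bisection to hit it.
#' @param artifact_rate fraction of minutes corrupted with out-of-range
#'   spikes or pressure-ordering violations.
#' @param dropout_rate fraction of minutes dropped entirely (gaps).
#' @param bolus_at_positive_prob probability that a CPOT >= 3 assessment
#'   triggers a fentanyl bolus.
#' @param bolus_response_prob probability a bolus recipient is a responder
#'   (latent severity decays to <= 0.5 of its value within 60 min).
#' @param assessment_interval_min scheduled CPOT interval, minutes
#'   (default 480 = every 8 h).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 100L,
                             duration_min = 2880L,
                             seed = 1L,
                             vitals_mean = c(hr = 80, sbp = 120, dbp = 65, rr = 16, spo2 = 97),
                             vitals_sd = c(hr = 10, sbp = 12, dbp = 7, rr = 2.5, spo2 = 1),
                             drift_magnitude = c(hr = 15, sbp = 20, dbp = 10, rr = 4, spo2 = -2),
                             drift_half_life_min = 15,
                             noise_sd = c(hr = 3, sbp = 5, dbp = 3, rr = 1.5, spo2 = 0.8),
                             ar1_coefficient = 0,
                             pain_episode_rate = 0.017,
                             pain_effect = c(hr = 10, sbp = 12, dbp = 6, rr = 4, spo2 = 0),
                             target_positive_rate = 0.033,
                             artifact_rate = 0.02,
                             dropout_rate = 0.02,
                             bolus_at_positive_prob = 0.5,
                             bolus_response_prob = 0.3,
                             assessment_interval_min = 480L) {
  base_vitals <- c("hr", "sbp", "dbp", "rr", "spo2")
  need_named <- function(x, name) {
    if (!all(base_vitals %in% names(x)))
      stop(sprintf("invalid config: '%s' must be named with %s", name,
                   paste(base_vitals, collapse = ", ")), call. = FALSE)
    x[base_vitals]
  }
  vitals_mean <- need_named(vitals_mean, "vitals_mean")
  vitals_sd <- need_named(vitals_sd, "vitals_sd")
  drift_magnitude <- need_named(drift_magnitude, "drift_magnitude")
  noise_sd <- need_named(noise_sd, "noise_sd")
  pain_effect <- need_named(pain_effect, "pain_effect")

  chk <- function(ok, field, what) {
    if (!isTRUE(ok))
      stop(sprintf("invalid config: '%s' %s", field, what), call. = FALSE)
  }
  chk(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 1,
      "n_patients", "must be a positive count")
  chk(is.numeric(duration_min) && length(duration_min) == 1 && duration_min >= 120,
      "duration_min", "must be >= 120 minutes")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a finite integer")
  chk(all(vitals_sd >= 0), "vitals_sd", "must be >= 0")
  chk(all(noise_sd >= 0), "noise_sd", "must be >= 0")
  chk(noise_sd[["sbp"]] >= noise_sd[["dbp"]], "noise_sd",
      "requires sbp >= dbp (pulse-pressure decomposition)")
  chk(vitals_sd[["sbp"]] >= vitals_sd[["dbp"]], "vitals_sd",
      "requires sbp >= dbp (pulse-pressure decomposition)")
  chk(drift_half_life_min > 0, "drift_half_life_min", "must be > 0")
  chk(ar1_coefficient >= 0 && ar1_coefficient < 1, "ar1_coefficient",
      "must be in [0, 1)")
  chk(pain_episode_rate >= 0, "pain_episode_rate", "must be >= 0")
  for (f in c("target_positive_rate", "artifact_rate", "dropout_rate",
              "bolus_at_positive_prob", "bolus_response_prob")) {
    v <- get(f)
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, f,
        "must be a fraction in [0, 1]")
  }
  chk(assessment_interval_min >= 1, "assessment_interval_min", "must be >= 1")

  structure(list(
    n_patients = as.integer(n_patients), duration_min = as.integer(duration_min),
    seed = as.integer(seed),
    vitals_mean = vitals_mean, vitals_sd = vitals_sd,
    drift_magnitude = drift_magnitude, drift_half_life_min = drift_half_life_min,
    noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
    pain_episode_rate = pain_episode_rate, pain_effect = pain_effect,
    target_positive_rate = target_positive_rate,
    artifact_rate = artifact_rate, dropout_rate = dropout_rate,
    bolus_at_positive_prob = bolus_at_positive_prob,
    bolus_response_prob = bolus_response_prob,
    assessment_interval_min = as.integer(assessment_interval_min)
  ), class = "generator_config")
}

#' Effective marginal observation-noise SD per vital, including derived MBP
#'
#' MBP = DBP + PP/3 with PP = SBP - DBP generated as an independent channel,
#' so sd(MBP noise) = sqrt(sd_dbp^2 + (sd_pp/3)^2) where
#' sd_pp = sqrt(sd_sbp^2 - sd_dbp^2).
#'
#' @param config a [generator_config()].
#' @return named numeric vector over hr, sbp, mbp, dbp, rr, spo2.
#' @export
noise_sd_effective <- function(config) {
  s <- config$noise_sd
  sd_pp <- sqrt(max(0, s[["sbp"]]^2 - s[["dbp"]]^2))
  c(hr = s[["hr"]], sbp = s[["sbp"]],
    mbp = sqrt(s[["dbp"]]^2 + (sd_pp / 3)^2),
    dbp = s[["dbp"]], rr = s[["rr"]], spo2 = s[["spo2"]])
}

# pain_effect / drift for the derived MBP channel
derived_mbp <- function(x) x[["dbp"]] + (x[["sbp"]] - x[["dbp"]]) / 3

# Marginal-variance AR(1) noise: e_t = rho e_{t-1} + sqrt(1-rho^2) z_t, sd-scaled.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n + 1)
  if (rho == 0) return(sd * z[-1])
  e <- stats::filter(sqrt(1 - rho^2) * z[-1], rho, method = "recursive",
                     init = z[1])
  sd * as.numeric(e)
}

# P(CPOT >= 3 | severity s) under CPOT = clamp(round(2s + eps), 0, 8),
# eps uniform on {-1, 0, 1}: round(x) >= 3 iff x >= 2.5 (a.s.).
positive_prob <- function(s) {
  ((2 * s >= 1.5) + (2 * s >= 2.5) + (2 * s >= 3.5)) / 3
}

severity_to_cpot <- function(sev, observer_noise = TRUE) {
  eps <- if (observer_noise) sample(c(-1L, 0L, 1L), length(sev), replace = TRUE)
         else 0L
  as.integer(clamp(round(2 * sev + eps), 0, 8))
}

# Bisection on the severity scale multiplier so that the expected positive
# fraction over the realized assessment severities matches the target.
calibrate_severity_scale <- function(sev_at_assess, target) {
  if (all(sev_at_assess <= 0) || target <= 0) return(1)
  f <- function(m) mean(positive_prob(m * sev_at_assess))
  lo <- 1e-3; hi <- 1e3
  if (f(hi) < target) {
    warning("target_positive_rate unreachable at configured episode rate; using maximal scale")
    return(hi)
  }
  if (f(lo) > target) return(lo)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Per-patient latent severity from overlapping persistent episodes: a
# 20-min onset ramp to a plateau that lasts until the end of monitoring
# (untreated ICU pain persists until treated), so severity is locally flat
# around analgesic boluses unless a responder decay is applied.
EPISODE_RAMP_MIN <- 20

episode_severity <- function(episodes, n) {
  sev <- numeric(n)
  if (nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      on <- episodes$onset[i]
      dur <- min(episodes$duration[i], n - on)
      if (dur <= 0) next
      idx <- seq(on, on + dur - 1)
      shape <- pmin(1, (idx - on + 0.5) / EPISODE_RAMP_MIN)
      sev[idx + 1] <- sev[idx + 1] + episodes$amplitude[i] * shape
    }
  }
  sev
}

# Slowly switching RASS chain over [-5, 4]; marginal mass near 0 and
# negative values (sedated ICU population).
RASS_STATES <- -5:4
RASS_MARGINAL <- c(0.038, 0.086, 0.108, 0.098, 0.159, 0.428,
                   0.057, 0.021, 0.004, 0.001)

simulate_rass_chain <- function(n, mean_dwell = 240) {
  out <- integer(n)
  t <- 0L
  while (t < n) {
    state <- sample(RASS_STATES, 1, prob = RASS_MARGINAL)
    dwell <- max(1L, as.integer(stats::rexp(1, 1 / mean_dwell)))
    idx <- seq.int(t, min(t + dwell, n) - 1L)
    out[idx + 1L] <- state
    t <- t + dwell
  }
  out
}

#' Simulate one patient's per-minute vital-sign stream
#'
#' Signal model per vital: true baseline + admission drift (exponentially
#' decaying) + AR(1) observation noise + `pain_effect` x latent severity.
#' SBP/MBP are built from independent DBP and pulse-pressure channels
#' (MBP = DBP + PP/3, PP clamped >= 5 mmHg), so DBP <= MBP <= SBP always
#' holds before artifact injection.
#'
#' @param profile list with scalar true baselines `hr0`, `dbp0`, `pp0`,
#'   `rr0`, `spo2_0` and a per-minute `severity` vector (length
#'   `config$duration_min`, zeros allowed).
#' @param config a [generator_config()].
#' @param patient_id identifier placed in the output.
#' @return data.frame with columns patient_id, t_min, hr, sbp, mbp, dbp,
#'   rr, spo2 on the full integer-minute grid `0:(duration_min-1)`.
#' @export
generate_patient_vitals <- function(profile, config, patient_id = "P0001") {
  n <- config$duration_min
  sev <- profile$severity %||% numeric(n)
  stopifnot(length(sev) == n)
  decay <- 2^(-(0:(n - 1)) / config$drift_half_life_min)
  dm <- config$drift_magnitude; ns <- config$noise_sd; pe <- config$pain_effect
  rho <- config$ar1_coefficient
  sd_pp <- sqrt(max(0, ns[["sbp"]]^2 - ns[["dbp"]]^2))

  hr <- profile$hr0 + dm[["hr"]] * decay + ar1_noise(n, ns[["hr"]], rho) +
    pe[["hr"]] * sev
  dbp <- profile$dbp0 + dm[["dbp"]] * decay + ar1_noise(n, ns[["dbp"]], rho) +
    pe[["dbp"]] * sev
  pp <- profile$pp0 + (dm[["sbp"]] - dm[["dbp"]]) * decay +
    ar1_noise(n, sd_pp, rho) + (pe[["sbp"]] - pe[["dbp"]]) * sev
  pp <- pmax(pp, 5)
  sbp <- dbp + pp
  mbp <- dbp + pp / 3
  rr <- pmax(profile$rr0 + dm[["rr"]] * decay + ar1_noise(n, ns[["rr"]], rho) +
               pe[["rr"]] * sev, 3)
  spo2 <- pmin(profile$spo2_0 + dm[["spo2"]] * decay +
                 ar1_noise(n, ns[["spo2"]], rho) + pe[["spo2"]] * sev, 100)

  data.frame(patient_id = patient_id, t_min = 0:(n - 1),
             hr = hr, sbp = sbp, mbp = mbp, dbp = dbp, rr = rr, spo2 = spo2,
             stringsAsFactors = FALSE)
}

#' Emit CPOT/RASS assessments from a latent severity series
#'
#' CPOT is a clamped rounding of a calibrated monotone map of severity
#' (`CPOT = clamp(round(2 * severity + eps), 0, 8)`) with integer observer
#' noise `eps` uniform on \{-1, 0, 1\}; RASS is read from a per-minute series
#' (or drawn i.i.d. from the marginal ICU distribution when absent).
#'
#' @param severity per-minute latent severity, `>= 0`, minute 0 first.
#' @param schedule integer assessment minutes; values in
#'   `[0, length(severity)]` (an assessment on the minute boundary after the
#'   last sample reads the last sample).
#' @param rass optional per-minute integer RASS series.
#' @param observer_noise logical; disable for deterministic CPOT.
#' @param cam_icu_rate probability of a positive CAM-ICU screen when charted.
#' @return data.frame(t_min, cpot, rass, cam_icu).
#' @export
emit_assessments <- function(severity, schedule, rass = NULL,
                             observer_noise = TRUE, cam_icu_rate = 0.2) {
  n <- length(severity)
  if (any(schedule < 0 | schedule > n))
    stop("schedule outside stream time range [0, ", n, "]")
  idx <- pmin(schedule, n - 1) + 1
  cpot <- severity_to_cpot(severity[idx], observer_noise)
  r <- if (is.null(rass)) {
    sample(RASS_STATES, length(schedule), replace = TRUE, prob = RASS_MARGINAL)
  } else rass[idx]
  cam <- ifelse(r >= -3,
                ifelse(stats::runif(length(schedule)) < cam_icu_rate,
                       "positive", "negative"),
                NA_character_)
  data.frame(t_min = as.integer(schedule), cpot = cpot, rass = as.integer(r),
             cam_icu = cam, stringsAsFactors = FALSE)
}

#' Corrupt a vital stream with artifacts and dropout
#'
#' Corrupted minutes carry an out-of-plausible-range spike in one vital or a
#' violated pressure ordering (SBP/DBP swapped); dropped minutes are removed
#' from the grid entirely. Every corrupted minute violates at least one
#' default noise-filter rule, so [apply_noise_filter()] removes it whole.
#'
#' @param stream per-patient vitals data.frame as from
#'   [generate_patient_vitals()].
#' @param artifact_rate,dropout_rate fractions in `[0, 1]`.
#' @return the stream with corrupted values and dropped rows; attribute
#'   `"corrupted"` is a data.frame(t_min, vital) of injected artifacts
#'   (restricted to rows that survived dropout).
#' @export
inject_artifacts <- function(stream, artifact_rate, dropout_rate) {
  n <- nrow(stream)
  corrupt <- which(stats::runif(n) < artifact_rate)
  kinds <- c("hr", "sbp", "dbp", "rr", "spo2", "order")
  kind <- sample(kinds, length(corrupt), replace = TRUE)
  for (j in seq_along(corrupt)) {
    i <- corrupt[j]
    switch(kind[j],
      hr = stream$hr[i] <- sample(c(stats::runif(1, 260, 400), stats::runif(1, 0, 15)), 1),
      sbp = stream$sbp[i] <- stats::runif(1, 310, 450),
      dbp = stream$dbp[i] <- stats::runif(1, 210, 300),
      rr = stream$rr[i] <- sample(c(stats::runif(1, 65, 120), stats::runif(1, 0, 1.5)), 1),
      spo2 = stream$spo2[i] <- stats::runif(1, 15, 45),
      order = {
        tmp <- stream$sbp[i]
        stream$sbp[i] <- stream$dbp[i]
        stream$dbp[i] <- tmp
      })
  }
  drop <- which(stats::runif(n) < dropout_rate)
  corrupted <- data.frame(t_min = stream$t_min[corrupt], vital = kind,
                          stringsAsFactors = FALSE)
  if (length(drop)) {
    corrupted <- corrupted[!corrupted$t_min %in% stream$t_min[drop], , drop = FALSE]
    stream <- stream[-drop, , drop = FALSE]
  }
  rownames(stream) <- NULL
  attr(stream, "corrupted") <- corrupted
  stream
}

# Post-bolus severity attenuation for responders: halves within 30 min,
# floored at 0.3 (sustained partial analgesia).
responder_decay <- function(delta_min) pmax(0.3, 2^(-delta_min / 30))

#' Generate a synthetic ICU cohort with known ground truth
#'
#' Produces per-minute vital streams, CPOT/RASS/CAM-ICU assessments
#' (scheduled every `assessment_interval_min`, one within 5 min of each
#' episode onset, and a follow-up 60 min after each bolus), fentanyl bolus
#' events with latent responder status, demographics, and the full ground
#' truth (true baselines, calibrated severity series, episodes, corrupted
#' minutes). The episode severity scale is calibrated by bisection so the
#' expected CPOT >= 3 fraction matches `target_positive_rate`.
#'
#' @param config a [generator_config()].
#' @return list of class `icu_cohort` with elements `vitals`, `assessments`,
#'   `events`, `demographics`, `ground_truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$duration_min
  np <- config$n_patients
  ids <- sprintf("P%04d", seq_len(np))
  vm <- config$vitals_mean; vs <- config$vitals_sd

  # Phase A: profiles, episodes, schedules ---------------------------------
  profiles <- vector("list", np)
  episodes_all <- vector("list", np)
  sev_raw <- vector("list", np)
  sched_all <- vector("list", np)
  for (p in seq_len(np)) {
    grp <- sample(c("20-44", "45-64", "65+"), 1, prob = c(0.2, 0.3, 0.5))
    age <- switch(grp, "20-44" = sample(20:44, 1), "45-64" = sample(45:64, 1),
                  sample(65:89, 1))
    sex <- sample(c("male", "female"), 1, prob = c(0.58, 0.42))
    dbp0 <- clamp(stats::rnorm(1, vm[["dbp"]], vs[["dbp"]]), 40, 95)
    sd_pp0 <- sqrt(max(1, vs[["sbp"]]^2 - vs[["dbp"]]^2))
    pp0 <- max(25, stats::rnorm(1, vm[["sbp"]] - vm[["dbp"]], sd_pp0))
    profiles[[p]] <- list(
      age = age, sex = sex,
      hr0 = clamp(stats::rnorm(1, vm[["hr"]], vs[["hr"]]), 45, 130),
      dbp0 = dbp0, pp0 = pp0,
      rr0 = clamp(stats::rnorm(1, vm[["rr"]], vs[["rr"]]), 8, 28),
      spo2_0 = clamp(stats::rnorm(1, vm[["spo2"]], vs[["spo2"]]), 90, 100))
    n_ep <- stats::rpois(1, config$pain_episode_rate * n / 60)
    # onsets only after a 3-h admission stabilization period (admission
    # analgesia/sedation load); episodes persist to the end of monitoring
    onset_lo <- min(180L, n - 60L)
    onset_hi <- n - 60L
    if (onset_hi < onset_lo) n_ep <- 0L
    onset <- if (n_ep > 0)
      sort(sample(seq.int(onset_lo, onset_hi), n_ep, replace = TRUE))
    else integer(0)
    ep <- data.frame(
      onset = onset,
      duration = n - onset,
      amplitude = stats::rgamma(n_ep, shape = 4, scale = 0.3) + 0.2)
    episodes_all[[p]] <- ep
    sev_raw[[p]] <- episode_severity(ep, n)
    sched <- if (config$assessment_interval_min <= n)
      seq.int(config$assessment_interval_min, n,
              by = config$assessment_interval_min)
    else integer(0)
    trig <- if (nrow(ep)) pmin(ep$onset + sample(0:5, nrow(ep), replace = TRUE),
                               n) else integer(0)
    sched_all[[p]] <- sort(unique(c(sched, trig)))
  }

  # Phase B: calibrate severity scale over all assessment minutes ----------
  sev_assess <- unlist(lapply(seq_len(np), function(p)
    sev_raw[[p]][pmin(sched_all[[p]], n - 1) + 1]))
  m <- calibrate_severity_scale(sev_assess, config$target_positive_rate)

  # Phase C: interleaved assessment / bolus emission with responder decay --
  assessments <- vector("list", np)
  events <- vector("list", np)
  gt_boluses <- vector("list", np)
  severity_final <- vector("list", np)
  rass_series <- vector("list", np)
  for (p in seq_len(np)) {
    rass <- simulate_rass_chain(n)
    rass_series[[p]] <- rass
    resp <- rep(1, n)
    queue <- sched_all[[p]]
    rows <- list(); brows <- list(); last_bolus <- -Inf
    while (length(queue)) {
      t <- queue[1]; queue <- queue[-1]
      i <- min(t, n - 1) + 1
      sev_t <- m * sev_raw[[p]][i] * resp[i]
      cpot <- severity_to_cpot(sev_t, TRUE)
      r <- rass[i]
      cam <- if (r >= -3) {
        if (stats::runif(1) < 0.2) "positive" else "negative"
      } else NA_character_
      rows[[length(rows) + 1]] <- list(t_min = as.integer(t), cpot = cpot,
                                       rass = as.integer(r), cam_icu = cam)
      if (cpot >= 3 && t - last_bolus > 120 && t + 60 <= n &&
          stats::runif(1) < config$bolus_at_positive_prob) {
        dose <- sample(c(25, 50, 100), 1)
        responder <- stats::runif(1) < config$bolus_response_prob
        brows[[length(brows) + 1]] <- list(t_min = as.integer(t), dose_ug = dose,
                                           responder = responder)
        last_bolus <- t
        if (responder) {
          idx <- seq(t, n - 1)
          resp[idx + 1] <- resp[idx + 1] * responder_decay(idx - t)
        }
        queue <- sort(unique(c(queue, t + 60)))
      }
    }
    a <- if (length(rows))
      do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
    else data.frame(t_min = integer(0), cpot = integer(0), rass = integer(0),
                    cam_icu = character(0), stringsAsFactors = FALSE)
    a <- a[order(a$t_min), , drop = FALSE]
    a <- a[!duplicated(a$t_min), , drop = FALSE]
    assessments[[p]] <- data.frame(patient_id = rep(ids[p], nrow(a)), a,
                                   stringsAsFactors = FALSE)
    b <- if (length(brows)) do.call(rbind.data.frame,
                                    c(brows, stringsAsFactors = FALSE))
         else data.frame(t_min = integer(0), dose_ug = numeric(0),
                         responder = logical(0))
    gt_boluses[[p]] <- cbind(patient_id = rep(ids[p], nrow(b)), b,
                             stringsAsFactors = FALSE)
    events[[p]] <- data.frame(patient_id = rep(ids[p], nrow(b)),
                              t_min = b$t_min, drug = rep("fentanyl", nrow(b)),
                              dose_ug = b$dose_ug, stringsAsFactors = FALSE)
    severity_final[[p]] <- m * sev_raw[[p]] * resp
  }

  # Phase D: vitals + artifacts --------------------------------------------
  vitals <- vector("list", np)
  corrupted <- vector("list", np)
  for (p in seq_len(np)) {
    prof <- profiles[[p]]
    prof$severity <- severity_final[[p]]
    v <- generate_patient_vitals(prof, config, patient_id = ids[p])
    v <- inject_artifacts(v, config$artifact_rate, config$dropout_rate)
    co <- attr(v, "corrupted")
    corrupted[[p]] <- cbind(patient_id = rep(ids[p], nrow(co)), co,
                            stringsAsFactors = FALSE)
    attr(v, "corrupted") <- NULL
    vitals[[p]] <- v
  }

  demographics <- data.frame(
    patient_id = ids,
    age = vapply(profiles, `[[`, numeric(1), "age"),
    sex = vapply(profiles, `[[`, character(1), "sex"),
    stringsAsFactors = FALSE)
  true_baselines <- data.frame(
    patient_id = ids,
    hr = vapply(profiles, `[[`, numeric(1), "hr0"),
    sbp = vapply(profiles, function(x) x$dbp0 + x$pp0, numeric(1)),
    mbp = vapply(profiles, function(x) x$dbp0 + x$pp0 / 3, numeric(1)),
    dbp = vapply(profiles, `[[`, numeric(1), "dbp0"),
    rr = vapply(profiles, `[[`, numeric(1), "rr0"),
    spo2 = vapply(profiles, `[[`, numeric(1), "spo2_0"),
    stringsAsFactors = FALSE)

  structure(list(
    vitals = do.call(rbind, vitals),
    assessments = do.call(rbind, assessments),
    events = do.call(rbind, events),
    demographics = demographics,
    ground_truth = list(
      true_baselines = true_baselines,
      severity = stats::setNames(severity_final, ids),
      rass = stats::setNames(rass_series, ids),
      episodes = stats::setNames(episodes_all, ids),
      boluses = do.call(rbind, gt_boluses),
      corrupted = do.call(rbind, corrupted),
      severity_scale = m),
    config = config), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d patients, %d min each\n",
              x$config$n_patients, x$config$duration_min))
  cat(sprintf("  vitals rows: %d  assessments: %d (%.1f%% CPOT >= 3)  boluses: %d\n",
              nrow(x$vitals), nrow(x$assessments),
              100 * mean(x$assessments$cpot >= 3), nrow(x$events)))
  invisible(x)
}
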