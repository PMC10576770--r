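#' Extract and complete the 1-h window preceding an assessment
#'
#' Returns the per-minute series over `[t - width_min, t)`. The coverage
#' gate here is strict (`> coverage_threshold`, i.e. more than 90% of the
#' hour by default); gaps are completed as in [interpolate_gaps()]. The
#' window is rejected when the assessment precedes baseline establishment:
#' no pain index exists before the baseline does.
#'
#' @param series one vital's per-minute values indexed by `t_min + 1`
#'   (`NA` for gaps), as produced internally from a vitals stream.
#' @param t assessment minute.
#' @param established_at minute the patient's baseline was established.
#' @param width_min window width (default 60).
#' @param coverage_threshold strict lower bound on the present fraction.
#' @return list with `ok`; on success `values`, else `reason`
#'   (`"before_baseline"` or `"coverage"`).
#' @export
extract_window <- function(series, t, established_at, width_min = 60L,
                           coverage_threshold = 0.90) {
  if (is.na(established_at) || t < established_at)
    return(list(ok = FALSE, reason = "before_baseline"))
  if (t - width_min < 0) return(list(ok = FALSE, reason = "before_baseline"))
  idx <- (t - width_min):(t - 1) + 1
  win <- rep(NA_real_, width_min)
  ok_idx <- idx >= 1 & idx <= length(series)
  win[ok_idx] <- series[idx[ok_idx]]
  interpolate_gaps(win, coverage_threshold, strict = TRUE)
}

#' Deviation-from-baseline summaries over a completed window
#'
#' With `d(t) = series(t) - baseline_value`: `area_above` is the trapezoidal
#' integral of `max(d, 0)` over the window (unit x min), `area_below` that of
#' `max(-d, 0)`, `mean_dev` the mean deviation, and `dev_at_t` the deviation
#' at the final window minute.
#'
#' @param series completed numeric series (no gaps).
#' @param baseline_value scalar baseline for this vital.
#' @return list with `area_above`, `area_below`, `mean_dev`, `dev_at_t`.
#' @export
deviation_areas <- function(series, baseline_value) {
  d <- series - baseline_value
  n <- length(d)
  pos <- pmax(d, 0); neg <- pmax(-d, 0)
  list(area_above = sum((pos[-1] + pos[-n]) / 2),
       area_below = sum((neg[-1] + neg[-n]) / 2),
       mean_dev = mean(d),
       dev_at_t = d[n])
}

#' Stratify age into the study's three groups
#'
#' Inclusive bounds: 20-44, 45-64, 65+. The study population is adults aged
#' 20 years or older; younger ages are rejected.
#'
#' @param age_years numeric age(s) in years.
#' @return character vector of group labels.
#' @export
stratify_age <- function(age_years) {
  if (any(age_years < 20))
    stop("age below 20 is outside the study population")
  ifelse(age_years <= 44, "20-44", ifelse(age_years <= 64, "45-64", "65+"))
}

#' Binary pain label from a CPOT score
#'
#' CPOT >= 3 is positive for pain; CPOT <= 2 negative.
#'
#' @param cpot integer CPOT score(s) in `[0, 8]`.
#' @return factor with levels `negative`, `positive`.
#' @export
label_assessment <- function(cpot) {
  stopifnot(all(cpot >= 0 & cpot <= 8))
  factor(ifelse(cpot >= 3, "positive", "negative"),
         levels = c("negative", "positive"))
}

feature_names <- function(vitals = MODEL_VITALS) {
  as.vector(t(outer(vitals, c("value", "dev", "area_above", "area_below",
                              "mean_dev"), paste, sep = "_")))
}

#' Build the per-assessment feature table
#'
#' One row per CPOT assessment that passes window extraction for every model
#' vital: per-vital `{value, dev, area_above, area_below, mean_dev}` against
#' the patient baseline, plus sex, age group, and the RASS score (same-time,
#' else nearest within `rass_tol_min`), with the binary pain label. Every
#' dropped assessment is logged with a reason.
#'
#' @param vitals (noise-filtered) vitals data.frame.
#' @param baselines result of [establish_baselines()] (or its `objects`).
#' @param assessments assessments data.frame with `cpot` and `rass`.
#' @param demographics data.frame(patient_id, age, sex).
#' @param width_min feature window width (default 60).
#' @param coverage_threshold strict coverage gate (default 0.90).
#' @param rass_tol_min RASS matching tolerance in minutes (default 60).
#' @return list with `features` (data.frame) and `drops`
#'   (data.frame patient_id, t_min, reason).
#' @export
build_feature_table <- function(vitals, baselines, assessments, demographics,
                                width_min = 60L, coverage_threshold = 0.90,
                                rass_tol_min = 60L) {
  objs <- if (!is.null(baselines$objects)) baselines$objects else baselines
  unknown <- setdiff(unique(assessments$patient_id), names(objs))
  if (length(unknown))
    stop("unknown patient_id in assessments: ", paste(unknown, collapse = ", "))
  fnames <- feature_names()
  rows <- list(); drops <- list()
  note_drop <- function(pid, t, reason)
    drops[[length(drops) + 1]] <<- list(patient_id = pid, t_min = t,
                                        reason = reason)
  for (pid in unique(assessments$patient_id)) {
    b <- objs[[pid]]
    a <- assessments[assessments$patient_id == pid, , drop = FALSE]
    demo <- demographics[demographics$patient_id == pid, , drop = FALSE]
    if (nrow(demo) != 1) stop("missing demographics for patient ", pid)
    pv <- vitals[vitals$patient_id == pid, , drop = FALSE]
    series <- if (nrow(pv)) stream_to_series(pv) else NULL
    rass_known <- a[!is.na(a$rass), c("t_min", "rass")]
    for (i in seq_len(nrow(a))) {
      t <- a$t_min[i]
      if (is.na(a$cpot[i])) { note_drop(pid, t, "no_label"); next }
      if (is.null(b) || !b$established) { note_drop(pid, t, "no_baseline"); next }
      if (t < b$established_at) { note_drop(pid, t, "before_baseline"); next }
      # RASS: same-time else nearest within tolerance
      rass <- a$rass[i]
      if (is.na(rass)) {
        if (nrow(rass_known)) {
          dist <- abs(rass_known$t_min - t)
          j <- which.min(dist)
          if (dist[j] <= rass_tol_min) rass <- rass_known$rass[j]
        }
        if (is.na(rass)) { note_drop(pid, t, "no_rass"); next }
      }
      feats <- stats::setNames(numeric(length(fnames)), fnames)
      ok <- TRUE
      for (v in MODEL_VITALS) {
        win <- extract_window(series[[v]], t, b$established_at, width_min,
                              coverage_threshold)
        if (!win$ok) {
          note_drop(pid, t, if (win$reason == "coverage") "low_coverage"
                            else win$reason)
          ok <- FALSE; break
        }
        dv <- deviation_areas(win$values, b$baselines[[v]])
        feats[paste0(v, "_value")] <- win$values[length(win$values)]
        feats[paste0(v, "_dev")] <- dv$dev_at_t
        feats[paste0(v, "_area_above")] <- dv$area_above
        feats[paste0(v, "_area_below")] <- dv$area_below
        feats[paste0(v, "_mean_dev")] <- dv$mean_dev
      }
      if (!ok) next
      rows[[length(rows) + 1]] <- c(
        list(patient_id = pid, t_min = t), as.list(feats),
        list(sex = demo$sex, age_group = stratify_age(demo$age),
             rass = as.integer(rass), cpot = as.integer(a$cpot[i])))
    }
  }
  drops_df <- if (length(drops))
    do.call(rbind.data.frame, c(drops, stringsAsFactors = FALSE))
  else data.frame(patient_id = character(0), t_min = integer(0),
                  reason = character(0), stringsAsFactors = FALSE)
  if (!length(rows)) {
    return(list(features = data.frame(), drops = drops_df))
  }
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  df$label <- label_assessment(df$cpot)
  rownames(df) <- NULL
  list(features = df, drops = drops_df)
}

# Numeric model matrix: 25 continuous deviation features + ordinal RASS +
# one-hot sex/age. Column order is the model schema.
feature_matrix <- function(features) {
  fn <- feature_names()
  X <- as.matrix(features[, fn, drop = FALSE])
  X <- cbind(X,
             rass = as.numeric(features$rass),
             sex_male = as.numeric(features$sex == "male"),
             age_45_64 = as.numeric(features$age_group == "45-64"),
             age_65p = as.numeric(features$age_group == "65+"))
  X
}

# Columns of the model matrix that are continuous for ADASYN interpolation.
continuous_feature_cols <- function() feature_names()
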