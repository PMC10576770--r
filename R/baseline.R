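#' Configuration for baseline stability detection
#'
#' Parameters of the five-step baseline establishment: candidate 1-h windows
#' are scanned from admission; a window is accepted when every model vital
#' passes a coverage gate, a Friedman rank test across three chronological
#' 20-min segments, and a coefficient-of-variation gate. On any failure the
#' window start advances by `retry_delay_min`.
#'
#' @param window_min window length in minutes (default 60).
#' @param coverage_threshold minimum present fraction of window minutes
#'   (inclusive gate, default 0.90).
#' @param n_segments number of chronological segments for the Friedman test.
#' @param friedman_alpha significance level; the window is unstable when the
#'   Friedman p-value falls below it.
#' @param cv_thresholds per-vital maximum coefficient of variation
#'   (sample SD / mean), boundary inclusive.
#' @param retry_delay_min advance of the window start after a failure.
#' @param anchor_span_min the baseline value is the mean of this many final
#'   minutes of the accepted (interpolated) window.
#' @param vitals vitals that must all pass the gates (SpO2 excluded by
#'   default: it is not an explanatory variable of the model).
#' @return an object of class `stability_config`.
#' @export
stability_config <- function(window_min = 60L, coverage_threshold = 0.90,
                             n_segments = 3L, friedman_alpha = 0.05,
                             cv_thresholds = c(hr = 0.10, sbp = 0.10, mbp = 0.10,
                                               dbp = 0.10, rr = 0.20, spo2 = 0.02),
                             retry_delay_min = 20L, anchor_span_min = 5L,
                             vitals = c("hr", "sbp", "mbp", "dbp", "rr")) {
  stopifnot(window_min %% n_segments == 0,
            coverage_threshold > 0, coverage_threshold <= 1,
            friedman_alpha > 0, friedman_alpha < 1,
            all(cv_thresholds > 0),
            retry_delay_min >= 1, anchor_span_min >= 1,
            anchor_span_min <= window_min,
            all(vitals %in% names(cv_thresholds)))
  structure(list(window_min = as.integer(window_min),
                 coverage_threshold = coverage_threshold,
                 n_segments = as.integer(n_segments),
                 friedman_alpha = friedman_alpha,
                 cv_thresholds = cv_thresholds,
                 retry_delay_min = as.integer(retry_delay_min),
                 anchor_span_min = as.integer(anchor_span_min),
                 vitals = vitals), class = "stability_config")
}

#' Complete a fixed-length per-minute window by two-tailed linear completion
#'
#' If the present fraction meets the coverage gate, interior gaps are
#' linearly interpolated between the nearest present neighbors and
#' leading/trailing gaps are filled by nearest-value extension (both
#' directions); otherwise the window is rejected with reason `"coverage"`.
#'
#' @param values numeric vector of fixed window length, `NA` for gaps.
#' @param coverage_threshold required present fraction.
#' @param strict if `TRUE` the gate is strict (`> threshold`, used for the
#'   pre-assessment feature window); default inclusive (`>=`, used for
#'   baseline establishment).
#' @return list with `ok`; on success `values` (completed series), on
#'   rejection `reason`.
#' @export
interpolate_gaps <- function(values, coverage_threshold = 0.90, strict = FALSE) {
  n <- length(values)
  present <- which(!is.na(values))
  frac <- length(present) / n
  pass <- if (strict) frac > coverage_threshold else frac >= coverage_threshold
  if (!length(present) || !pass)
    return(list(ok = FALSE, reason = "coverage", coverage = frac))
  if (length(present) == n)
    return(list(ok = TRUE, values = values, coverage = 1))
  if (length(present) == 1L) {
    filled <- rep(values[present], n)
  } else {
    # approx with rule = 2: linear interior, constant (nearest) extension
    filled <- stats::approx(present, values[present], xout = seq_len(n),
                            method = "linear", rule = 2)$y
  }
  list(ok = TRUE, values = filled, coverage = frac)
}

#' Friedman rank test for stability across chronological segments
#'
#' Splits the completed window into `n_segments` equal contiguous segments
#' (treatments) blocked by within-segment minute position, and applies the
#' Friedman rank test. The window is judged stable when `p >= alpha`.
#'
#' @param series completed numeric series; length must be divisible by
#'   `n_segments`.
#' @param n_segments number of chronological segments (default 3).
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `stable`.
#' @export
friedman_stability <- function(series, n_segments = 3L, alpha = 0.05) {
  n <- length(series)
  if (n %% n_segments != 0)
    stop("series length ", n, " not divisible into ", n_segments, " equal segments")
  m <- matrix(series, ncol = n_segments)  # column j = j-th chronological segment
  if (all(apply(m, 1, function(r) length(unique(r)) == 1L))) {
    # every block fully tied: no evidence of inter-segment difference
    return(list(statistic = 0, p_value = 1, stable = TRUE))
  }
  ft <- stats::friedman.test(m)
  p <- ft$p.value
  list(statistic = unname(ft$statistic), p_value = p, stable = p >= alpha)
}

#' Coefficient-of-variation stability gate
#'
#' `cv = sample SD / mean`; the series is stable when `cv <= threshold`
#' (boundary inclusive).
#'
#' @param series completed numeric series with positive mean.
#' @param threshold maximum allowed CV.
#' @return list with `cv`, `stable`.
#' @export
cv_stability <- function(series, threshold) {
  mu <- mean(series)
  if (!is.finite(mu) || mu <= 0)
    stop("cv_stability requires a positive series mean (degenerate input)")
  cv <- stats::sd(series) / mu
  list(cv = cv, stable = cv <= threshold)
}

# Evaluate one candidate window for one patient; returns either
# list(ok=TRUE, anchors=named numeric) or list(ok=FALSE, reason=...).
evaluate_window <- function(series_by_vital, s, cfg) {
  w <- cfg$window_min
  anchors <- stats::setNames(numeric(length(cfg$vitals)), cfg$vitals)
  for (v in cfg$vitals) {
    win <- series_by_vital[[v]][s + seq_len(w)]  # minutes [s, s+w)
    comp <- interpolate_gaps(win, cfg$coverage_threshold, strict = FALSE)
    if (!comp$ok) return(list(ok = FALSE, reason = "coverage"))
    fr <- friedman_stability(comp$values, cfg$n_segments, cfg$friedman_alpha)
    if (!fr$stable) return(list(ok = FALSE, reason = "friedman"))
    cvr <- cv_stability(comp$values, cfg$cv_thresholds[[v]])
    if (!cvr$stable) return(list(ok = FALSE, reason = "cv"))
    anchors[v] <- mean(utils::tail(comp$values, cfg$anchor_span_min))
  }
  list(ok = TRUE, anchors = anchors)
}

stream_to_series <- function(stream) {
  tmax <- max(stream$t_min)
  out <- lapply(VITALS, function(v) {
    x <- rep(NA_real_, tmax + 1)
    x[stream$t_min + 1] <- stream[[v]]
    x
  })
  stats::setNames(out, VITALS)
}

#' Establish a per-patient vital-sign baseline
#'
#' Scans candidate windows `[s, s + window_min)` starting at `s = 0`,
#' advancing `s` by `retry_delay_min` on any gate failure. The first window
#' in which every model vital passes the coverage, Friedman and CV gates is
#' accepted; the per-vital baseline is the mean of the final
#' `anchor_span_min` minutes of the accepted (interpolated) window, treated
#' thereafter as a constant reference. No baseline is ever reported for a
#' patient with less than one window of data, so no pain index exists
#' immediately after ICU admission.
#'
#' @param stream one patient's (noise-filtered) vitals data.frame.
#' @param cfg a [stability_config()].
#' @return object of class `patient_baseline`: list with `patient_id`,
#'   `established` (logical), `established_at` (minute the accepted window
#'   ends), `baselines` (named per-vital values), and `attempts`
#'   (data.frame window_start, failure_reason).
#' @export
establish_baseline <- function(stream, cfg = stability_config()) {
  pid <- unique(stream$patient_id)
  stopifnot(length(pid) == 1)
  attempts <- list()
  fail <- function(reason) {
    structure(list(patient_id = pid, established = FALSE,
                   established_at = NA_integer_, baselines = NULL,
                   attempts = attempts_df(attempts), reason = reason),
              class = "patient_baseline")
  }
  if (nrow(stream) == 0 || max(stream$t_min) + 1 < cfg$window_min)
    return(fail("stream shorter than window"))
  series <- stream_to_series(stream)
  tmax <- max(stream$t_min)
  s <- 0L
  while (s + cfg$window_min <= tmax + 1) {
    res <- evaluate_window(series, s, cfg)
    if (res$ok) {
      attempts[[length(attempts) + 1]] <- list(window_start = s,
                                               failure_reason = "none")
      return(structure(list(patient_id = pid, established = TRUE,
                            established_at = s + cfg$window_min,
                            baselines = res$anchors,
                            attempts = attempts_df(attempts), reason = NA_character_),
                       class = "patient_baseline"))
    }
    attempts[[length(attempts) + 1]] <- list(window_start = s,
                                             failure_reason = res$reason)
    s <- s + cfg$retry_delay_min
  }
  fail("no stable window found")
}

attempts_df <- function(attempts) {
  if (!length(attempts))
    return(data.frame(window_start = integer(0), failure_reason = character(0),
                      stringsAsFactors = FALSE))
  data.frame(window_start = vapply(attempts, `[[`, numeric(1), "window_start"),
             failure_reason = vapply(attempts, `[[`, character(1), "failure_reason"),
             stringsAsFactors = FALSE)
}

#' Establish baselines for every patient in a cohort
#'
#' @param vitals (noise-filtered) vitals data.frame for one or many patients.
#' @param cfg a [stability_config()].
#' @return list with `baselines` (data.frame patient_id, established,
#'   established_at, `<vital>_base` columns) and `objects` (named list of
#'   `patient_baseline` objects including the attempt logs).
#' @export
establish_baselines <- function(vitals, cfg = stability_config()) {
  ids <- unique(vitals$patient_id)
  objs <- lapply(ids, function(pid)
    establish_baseline(vitals[vitals$patient_id == pid, , drop = FALSE], cfg))
  names(objs) <- ids
  rows <- lapply(objs, function(b) {
    vals <- stats::setNames(rep(NA_real_, length(cfg$vitals)),
                            paste0(cfg$vitals, "_base"))
    if (b$established) vals[] <- b$baselines[cfg$vitals]
    c(list(patient_id = b$patient_id, established = b$established,
           established_at = b$established_at), as.list(vals))
  })
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  list(baselines = df, objects = objs)
}

#' @export
print.patient_baseline <- function(x, ...) {
  if (x$established) {
    cat(sprintf("Baseline for %s established at minute %d after %d attempt(s)\n",
                x$patient_id, x$established_at, nrow(x$attempts)))
    print(round(x$baselines, 2))
  } else {
    cat(sprintf("Baseline for %s NOT established (%s)\n", x$patient_id, x$reason))
  }
  invisible(x)
}
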