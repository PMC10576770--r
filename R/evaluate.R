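as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels) || is.character(labels)) return(labels == "positive")
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  stop("labels must be logical, 0/1, or have level 'positive'")
}

#' Area under the ROC curve
#'
#' Computed as the pairwise concordance probability — a randomly chosen
#' positive outscores a randomly chosen negative, ties counted one half —
#' via the rank (Mann-Whitney) formula, equivalent to trapezoidal ROC
#' integration.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels positive/negative labels (factor, logical or 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and predictive values at a threshold
#'
#' Scores at or above the threshold are called positive. The default
#' threshold is the Youden-optimal point on the ROC (maximizing
#' sensitivity + specificity - 1). PPV/NPV are reported as `NA` when no
#' prediction of that sign exists.
#'
#' @param scores numeric scores.
#' @param labels positive/negative labels.
#' @param threshold operating threshold; `NULL` selects the Youden point.
#' @return list with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = NULL) {
  pos <- as_positive(labels)
  if (is.null(threshold)) threshold <- youden_threshold(scores, pos)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  list(threshold = threshold,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

youden_threshold <- function(scores, pos) {
  if (!any(pos) || all(pos)) stop("Youden threshold requires both classes")
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Harmonic mean of two accuracy metrics
#'
#' `2ab / (a + b)`, used to summarize sensitivity/specificity pairs.
#'
#' @param a,b values in `(0, 1]`.
#' @return the harmonic mean.
#' @export
harmonic_mean_metrics <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("harmonic mean undefined for non-positive input")
  2 * a * b / (a + b)
}

#' Qualitative AUROC band
#'
#' Low (0.5-0.7), moderate (0.7-0.8), high (>= 0.8); the boundaries 0.7 and
#' 0.8 fall upward (0.7 is moderate, 0.8 is high).
#'
#' @param auroc value in `[0, 1]`.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
classify_auroc <- function(auroc) {
  stopifnot(auroc >= 0, auroc <= 1)
  if (auroc >= 0.8) "high" else if (auroc >= 0.7) "moderate" else "low"
}

#' Group a bolus by CPOT improvement
#'
#' Improvement means the CPOT score decreased by at least 1 from the
#' pre-bolus to the post-bolus assessment.
#'
#' @param cpot_pre,cpot_post CPOT scores in `[0, 8]`.
#' @return `"improvement"` or `"non_improvement"` (vectorized).
#' @export
group_by_cpot_improvement <- function(cpot_pre, cpot_post) {
  stopifnot(all(cpot_pre >= 0 & cpot_pre <= 8),
            all(cpot_post >= 0 & cpot_post <= 8))
  ifelse(cpot_pre - cpot_post >= 1, "improvement", "non_improvement")
}

#' Treatment-response analysis around fentanyl boluses
#'
#' For each qualifying fentanyl bolus (dose within `dose_range`, no other
#' analgesic event within the trajectory window, pre- and post-bolus CPOT
#' available, pain index defined at t0 and t0+60 and over at least 90% of
#' the trajectory minutes): assigns the improvement group from the CPOT
#' change, builds per-group per-minute median/quartile pain-index
#' trajectories over `[t0 - 60, t0 + 60]`, and compares the pain index at
#' t0 versus t0+60 within each group (paired t and Wilcoxon signed-rank)
#' and between groups at t0+60 (Welch t and Wilcoxon rank-sum).
#' `cpot_pre` is the last CPOT in `[t0 - cpot_search_min, t0]`, `cpot_post`
#' the first in `(t0, t0 + cpot_search_min]`.
#'
#' @param pain_index data.frame(patient_id, t_min, pain_index), per minute.
#' @param events bolus events data.frame(patient_id, t_min, drug, dose_ug).
#' @param assessments assessments data.frame with `cpot`.
#' @param window_min trajectory half-width around the bolus (default 60).
#' @param cpot_search_min search half-width for pre/post CPOT (default 120).
#' @param dose_range inclusive fentanyl dose bounds in micrograms.
#' @return list with `records` (one row per qualifying bolus),
#'   `trajectories` (group, minute_rel, median, q25, q75, n),
#'   `comparisons` (within/between-group tests), `dropped` (bolus, reason).
#' @export
fentanyl_response_analysis <- function(pain_index, events, assessments,
                                       window_min = 60L, cpot_search_min = 120L,
                                       dose_range = c(25, 100)) {
  drops <- list(); recs <- list(); traj_rows <- list()
  note <- function(pid, t, reason)
    drops[[length(drops) + 1]] <<- list(patient_id = pid, t_min = t,
                                        reason = reason)
  fent <- events[events$drug == "fentanyl", , drop = FALSE]
  for (i in seq_len(nrow(fent))) {
    pid <- fent$patient_id[i]; t0 <- fent$t_min[i]
    if (fent$dose_ug[i] < dose_range[1] || fent$dose_ug[i] > dose_range[2]) {
      note(pid, t0, "dose_out_of_range"); next
    }
    other <- events[events$patient_id == pid &
                      abs(events$t_min - t0) <= window_min &
                      !(events$t_min == t0 & events$drug == "fentanyl"), ,
                    drop = FALSE]
    if (nrow(other)) { note(pid, t0, "other_analgesic_in_window"); next }
    a <- assessments[assessments$patient_id == pid & !is.na(assessments$cpot), ,
                     drop = FALSE]
    pre <- a[a$t_min >= t0 - cpot_search_min & a$t_min <= t0, , drop = FALSE]
    post <- a[a$t_min > t0 & a$t_min <= t0 + cpot_search_min, , drop = FALSE]
    if (!nrow(pre)) { note(pid, t0, "no_pre_cpot"); next }
    if (!nrow(post)) { note(pid, t0, "no_post_cpot"); next }
    cpot_pre <- pre$cpot[which.max(pre$t_min)]
    cpot_post <- post$cpot[which.min(post$t_min)]
    pi <- pain_index[pain_index$patient_id == pid &
                       pain_index$t_min >= t0 - window_min &
                       pain_index$t_min <= t0 + window_min, , drop = FALSE]
    pi_t0 <- pi$pain_index[pi$t_min == t0]
    pi_t60 <- pi$pain_index[pi$t_min == t0 + window_min]
    if (!length(pi_t0) || !length(pi_t60) ||
        nrow(pi) < 0.9 * (2 * window_min + 1)) {
      note(pid, t0, "pain_index_unavailable"); next
    }
    grp <- group_by_cpot_improvement(cpot_pre, cpot_post)
    recs[[length(recs) + 1]] <- list(patient_id = pid, t0 = t0,
                                     cpot_pre = cpot_pre, cpot_post = cpot_post,
                                     group = grp, pi_t0 = pi_t0, pi_t60 = pi_t60)
    traj_rows[[length(traj_rows) + 1]] <-
      data.frame(group = grp, minute_rel = pi$t_min - t0,
                 pain_index = pi$pain_index, stringsAsFactors = FALSE)
  }
  dropped <- if (length(drops))
    do.call(rbind.data.frame, c(drops, stringsAsFactors = FALSE))
  else data.frame(patient_id = character(0), t_min = integer(0),
                  reason = character(0), stringsAsFactors = FALSE)
  if (!length(recs))
    return(list(records = data.frame(), trajectories = data.frame(),
                comparisons = list(), dropped = dropped))
  records <- do.call(rbind.data.frame, c(recs, stringsAsFactors = FALSE))
  rownames(records) <- NULL
  traj <- do.call(rbind, traj_rows)
  agg <- stats::aggregate(pain_index ~ group + minute_rel, data = traj,
                          FUN = function(x) c(median = stats::median(x),
                                              q25 = stats::quantile(x, 0.25, names = FALSE),
                                              q75 = stats::quantile(x, 0.75, names = FALSE),
                                              n = length(x)))
  trajectories <- data.frame(group = agg$group, minute_rel = agg$minute_rel,
                             median = agg$pain_index[, "median"],
                             q25 = agg$pain_index[, "q25"],
                             q75 = agg$pain_index[, "q75"],
                             n = agg$pain_index[, "n"],
                             stringsAsFactors = FALSE)
  trajectories <- trajectories[order(trajectories$group,
                                     trajectories$minute_rel), , drop = FALSE]
  rownames(trajectories) <- NULL
  comparisons <- list()
  for (g in unique(records$group)) {
    rg <- records[records$group == g, , drop = FALSE]
    comparisons[[g]] <- list(
      n = nrow(rg),
      mean_t0 = mean(rg$pi_t0), sd_t0 = stats::sd(rg$pi_t0),
      mean_t60 = mean(rg$pi_t60), sd_t60 = stats::sd(rg$pi_t60),
      paired_t_p = if (nrow(rg) >= 2 && stats::sd(rg$pi_t0 - rg$pi_t60) > 0)
        stats::t.test(rg$pi_t0, rg$pi_t60, paired = TRUE)$p.value else NA_real_,
      # one-sided: is the pain index at t0+60 systematically BELOW t0?
      paired_t_p_drop = if (nrow(rg) >= 2 && stats::sd(rg$pi_t0 - rg$pi_t60) > 0)
        stats::t.test(rg$pi_t0, rg$pi_t60, paired = TRUE,
                      alternative = "greater")$p.value else NA_real_,
      wilcoxon_p = if (nrow(rg) >= 2 && any(rg$pi_t0 != rg$pi_t60))
        suppressWarnings(stats::wilcox.test(rg$pi_t0, rg$pi_t60,
                                            paired = TRUE)$p.value)
      else NA_real_)
  }
  both <- all(c("improvement", "non_improvement") %in% records$group)
  if (both) {
    gi <- records$pi_t60[records$group == "improvement"]
    gn <- records$pi_t60[records$group == "non_improvement"]
    comparisons$between_t60 <- list(
      welch_p = if (length(gi) >= 2 && length(gn) >= 2)
        stats::t.test(gi, gn)$p.value else NA_real_,
      wilcoxon_p = if (length(gi) >= 1 && length(gn) >= 1)
        suppressWarnings(stats::wilcox.test(gi, gn)$p.value) else NA_real_)
  }
  list(records = records, trajectories = trajectories,
       comparisons = comparisons, dropped = dropped)
}

#' Plot group pain-index trajectories around bolus administration
#'
#' Median trajectories with interquartile ribbons per improvement group,
#' time zero at bolus administration.
#'
#' @param trajectories the `trajectories` element of
#'   [fentanyl_response_analysis()].
#' @param file optional path; when given the plot is saved there (png).
#' @return the ggplot object, invisibly.
#' @export
plot_response_trajectories <- function(trajectories, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gg <- ggplot2::ggplot(trajectories,
                        ggplot2::aes(x = .data$minute_rel, y = 100 * .data$median,
                                     color = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$q25,
                                      ymax = 100 * .data$q75),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Minutes from fentanyl bolus", y = "Pain index (%)",
                  color = "CPOT group", fill = "CPOT group") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 7, height = 4.5, dpi = 150)
  invisible(gg)
}
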