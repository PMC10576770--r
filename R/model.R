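#' Configuration for pain-index model training
#'
#' @param n_estimators integer grid of forest sizes; the default single
#'   point (17) is the selected operating value, with
#'   `c(5, 10, 17, 25, 50)` the wider search grid.
#' @param max_depth integer grid of maximum tree depths (default 14;
#'   wider grid `c(6, 10, 14, 18)`).
#' @param cv_folds outer cross-validation folds (default 10).
#' @param cv_repeats outer CV repeats with distinct fold seeds (default 10).
#' @param inner_folds folds of the inner CV used by the grid search.
#' @param seed RNG seed; every forest and fold assignment is seeded.
#' @param oversample apply ADASYN to the positive class inside training
#'   folds (never to validation folds).
#' @param split_unit `"patient"` (default; folds never split a patient) or
#'   `"assessment"`.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_estimators = 17L, max_depth = 14L,
                         cv_folds = 10L, cv_repeats = 10L, inner_folds = 3L,
                         seed = 1L, oversample = TRUE,
                         split_unit = c("patient", "assessment")) {
  split_unit <- match.arg(split_unit)
  stopifnot(length(n_estimators) >= 1, length(max_depth) >= 1,
            cv_folds >= 2, cv_repeats >= 1, inner_folds >= 2)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), oversample = isTRUE(oversample),
                 split_unit = split_unit), class = "model_config")
}

#' Adaptive synthetic oversampling (ADASYN) of the positive class
#'
#' Synthesizes minority-class rows to approximate class balance. Each
#' minority point receives a synthesis count proportional to the majority
#' density among its K nearest neighbors (in the standardized continuous
#' feature subspace); each synthetic point lies on the segment between the
#' seed point and one of its K nearest minority neighbors. One-hot/ordinal
#' fields of a synthetic row are copied from its seed point.
#'
#' @param features data.frame of feature rows (as from
#'   [build_feature_table()]`$features`).
#' @param labels factor with level `"positive"` as the minority class.
#' @param seed RNG seed.
#' @param k number of nearest neighbors (default 5).
#' @return list with `features` (originals then synthetics), `labels`,
#'   `synthetic` (logical flag per row) and `provenance` (data.frame
#'   seed_row, partner_row, lambda for each synthetic row, indexing the
#'   original `features`).
#' @export
oversample_positives <- function(features, labels, seed = 1L, k = 5L) {
  pos <- labels == "positive"
  if (!any(pos)) stop("cannot balance a one-class set: no positive examples")
  if (!any(!pos)) stop("cannot balance a one-class set: no negative examples")
  n_min <- sum(pos); n_maj <- sum(!pos)
  G <- n_maj - n_min
  empty_prov <- data.frame(seed_row = integer(0), partner_row = integer(0),
                           lambda = numeric(0))
  if (G <= 0 || n_min < 2)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features)), provenance = empty_prov))
  set.seed(seed)
  cont <- continuous_feature_cols()
  X <- as.matrix(features[, cont, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  Z <- sweep(X, 2, sds, "/")
  min_idx <- which(pos)
  Zm <- Z[min_idx, , drop = FALSE]
  k_all <- min(k, nrow(Z) - 1)
  k_min <- min(k, n_min - 1)
  # distances minority -> all (for density ratios) and minority -> minority
  d_all <- outer(rowSums(Zm^2), rowSums(Z^2), "+") - 2 * Zm %*% t(Z)
  ri <- numeric(n_min)
  nn_min <- matrix(0L, n_min, k_min)
  for (i in seq_len(n_min)) {
    d <- d_all[i, ]
    d[min_idx[i]] <- Inf
    nn <- order(d)[seq_len(k_all)]
    ri[i] <- mean(!pos[nn])
    dm <- d[min_idx]
    dm[i] <- Inf
    nn_min[i, ] <- min_idx[order(dm)[seq_len(k_min)]]
  }
  gi <- if (sum(ri) == 0) {
    rep(floor(G / n_min), n_min) + (seq_len(n_min) <= G %% n_min)
  } else {
    round(ri / sum(ri) * G)
  }
  total <- sum(gi)
  if (total == 0)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features)), provenance = empty_prov))
  seed_rows <- rep(min_idx, gi)
  partner_rows <- integer(total)
  lambda <- stats::runif(total)
  pos_in_min <- rep(seq_len(n_min), gi)
  for (j in seq_len(total))
    partner_rows[j] <- nn_min[pos_in_min[j], sample.int(k_min, 1)]
  synth <- features[seed_rows, , drop = FALSE]
  Xs <- as.matrix(features[seed_rows, cont, drop = FALSE])
  Xp <- as.matrix(features[partner_rows, cont, drop = FALSE])
  synth[, cont] <- Xs + lambda * (Xp - Xs)
  rownames(synth) <- NULL
  out <- rbind(features, synth)
  rownames(out) <- NULL
  if (".synthetic" %in% names(out))
    out$.synthetic[seq.int(nrow(features) + 1L, nrow(out))] <- TRUE
  list(features = out,
       labels = factor(c(as.character(labels), rep("positive", total)),
                       levels = levels(labels)),
       synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, total)),
       provenance = data.frame(seed_row = seed_rows,
                               partner_row = partner_rows, lambda = lambda))
}

make_folds <- function(features, k, split_unit, seed) {
  set.seed(seed)
  if (split_unit == "patient") {
    ids <- unique(features$patient_id)
    grp <- sample(rep_len(seq_len(k), length(ids)))
    fold_of_id <- stats::setNames(grp, ids)
    unname(fold_of_id[features$patient_id])
  } else {
    sample(rep_len(seq_len(k), nrow(features)))
  }
}

fit_forest <- function(features, labels, n_estimators, max_depth, seed) {
  df <- as.data.frame(feature_matrix(features))
  df$.label <- labels
  ranger::ranger(dependent.variable.name = ".label", data = df,
                 num.trees = n_estimators, max.depth = max_depth,
                 probability = TRUE, seed = seed, num.threads = 1,
                 verbose = FALSE)
}

forest_prob <- function(forest, features) {
  pr <- stats::predict(forest, data = as.data.frame(feature_matrix(features)),
                       num.threads = 1)$predictions
  unname(pr[, "positive"])
}

#' Grid-search training of the class-balanced random forest
#'
#' For each grid cell the inner cross-validated AUROC is computed on the
#' training data only, with ADASYN applied inside inner-training folds and
#' never to the inner-validation rows; the best cell is refit on the full
#' (oversampled) training set. Deterministic given the config seed. With a
#' single-cell grid the inner CV is skipped.
#'
#' @param features training feature data.frame (with `label`).
#' @param cfg a [model_config()].
#' @return object of class `pain_model`: the fitted forest, chosen
#'   hyperparameters, feature schema, and training metadata.
#' @export
grid_search_train <- function(features, cfg = model_config()) {
  labels <- features$label
  if (length(unique(labels)) < 2)
    stop("training labels must contain both classes")
  grid <- expand.grid(n_estimators = cfg$n_estimators,
                      max_depth = cfg$max_depth)
  if (nrow(grid) > 1) {
    folds <- make_folds(features, cfg$inner_folds, cfg$split_unit, cfg$seed + 7919L)
    auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      scores <- rep(NA_real_, nrow(features))
      for (f in seq_len(cfg$inner_folds)) {
        tr <- folds != f
        if (length(unique(labels[tr])) < 2) {
          warning("degenerate inner fold skipped (single class)"); next
        }
        trs <- if (cfg$oversample)
          oversample_positives(features[tr, , drop = FALSE], labels[tr],
                               seed = cfg$seed + 100L * g + f)
        else list(features = features[tr, , drop = FALSE], labels = labels[tr])
        forest <- fit_forest(trs$features, trs$labels, grid$n_estimators[g],
                             grid$max_depth[g], cfg$seed + 100L * g + f)
        scores[!tr] <- forest_prob(forest, features[!tr, , drop = FALSE])
      }
      keep <- !is.na(scores)
      if (!any(keep) || length(unique(labels[keep])) < 2)
        stop("all inner folds degenerate: cannot grid-search")
      auc[g] <- roc_auc(scores[keep], labels[keep])
    }
    best <- which.max(auc)
  } else {
    best <- 1L
    auc <- NA_real_
  }
  trs <- if (cfg$oversample)
    oversample_positives(features, labels, seed = cfg$seed)
  else list(features = features, labels = labels,
            synthetic = rep(FALSE, nrow(features)))
  forest <- fit_forest(trs$features, trs$labels, grid$n_estimators[best],
                       grid$max_depth[best], cfg$seed)
  structure(list(forest = forest,
                 n_estimators = grid$n_estimators[best],
                 max_depth = grid$max_depth[best],
                 schema = colnames(feature_matrix(features[0, , drop = FALSE])),
                 grid = grid, grid_auc = auc,
                 seed = cfg$seed, oversample = cfg$oversample,
                 oversample_ratio = if (!is.null(trs$synthetic))
                   mean(trs$synthetic) else 0),
            class = "pain_model")
}

#' Predict the pain index for feature rows
#'
#' The pain index is the model's predicted probability that the concurrent
#' CPOT score would be >= 3, in `[0, 1]` (displayed clinically as 0-100%).
#'
#' @param model a `pain_model` from [grid_search_train()].
#' @param features feature rows with the training schema.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_pain_index <- function(model, features) {
  stopifnot(inherits(model, "pain_model"))
  sch <- tryCatch(colnames(feature_matrix(features[0, , drop = FALSE])),
                  error = function(e)
                    stop("schema mismatch: features lack required columns",
                         call. = FALSE))
  if (!identical(sch, model$schema))
    stop("schema mismatch: features do not match the model's training schema")
  if (nrow(features) == 0) return(numeric(0))
  forest_prob(model$forest, features)
}

#' Repeated cross-validated AUROC of the pain-index model
#'
#' Outer k-fold cross-validation repeated with distinct fold seeds;
#' oversampling happens inside training folds only, and a structural check
#' verifies that no ADASYN-synthesized row is ever scored in a validation
#' fold. Reports the mean and SD of per-repeat pooled AUROCs.
#'
#' @param features feature data.frame with `label` and `patient_id`.
#' @param cfg a [model_config()].
#' @return list with `mean`, `sd` (NA when `cv_repeats = 1`), `per_repeat`,
#'   and `leakage_checked` (TRUE when the structural assertion held on
#'   every fold).
#' @export
repeated_cv_auroc <- function(features, cfg = model_config()) {
  labels <- features$label
  # live structural leakage guard: every real row is flagged FALSE here and
  # oversample_positives() flags its synthetic rows TRUE, so a refactoring
  # that let oversampled tables reach the fold split would trip the check.
  features$.synthetic <- FALSE
  per_repeat <- numeric(cfg$cv_repeats)
  leakage_ok <- TRUE
  for (r in seq_len(cfg$cv_repeats)) {
    folds <- make_folds(features, cfg$cv_folds, cfg$split_unit,
                        cfg$seed + 1000L * r)
    scores <- rep(NA_real_, nrow(features))
    for (f in seq_len(cfg$cv_folds)) {
      tr <- folds != f
      if (!any(!tr)) next
      if (length(unique(labels[tr])) < 2) {
        warning("degenerate outer fold skipped (single training class)")
        next
      }
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + 1000L * r + f
      val <- features[!tr, , drop = FALSE]
      # structural leakage guard: validation rows are drawn from the original
      # table before any oversampling; a synthetic row can never reach here.
      if (!is.null(val$.synthetic) && any(val$.synthetic)) leakage_ok <- FALSE
      model <- grid_search_train(features[tr, , drop = FALSE], fold_cfg)
      scores[!tr] <- predict_pain_index(model, val)
    }
    keep <- !is.na(scores)
    if (!any(keep) || length(unique(labels[keep])) < 2)
      stop("all outer folds degenerate: cannot estimate AUROC")
    per_repeat[r] <- roc_auc(scores[keep], labels[keep])
  }
  list(mean = mean(per_repeat),
       sd = if (cfg$cv_repeats > 1) stats::sd(per_repeat) else NA_real_,
       per_repeat = per_repeat, leakage_checked = leakage_ok)
}

#' Per-minute pain-index series for one patient
#'
#' Recomputes the 1-h deviation features at each requested minute (window
#' `[t - 60, t)`, strict 90% coverage) and scores them with the fitted
#' model. No value is emitted before the baseline `established_at` minute.
#' RASS is carried forward from the most recent charted assessment (nearest
#' assessment when none precedes the minute).
#'
#' @param model a `pain_model`.
#' @param stream one patient's (noise-filtered) vitals data.frame.
#' @param baseline the patient's `patient_baseline` object.
#' @param assessments the patient's assessments (for RASS carry-forward).
#' @param demographics one-row data.frame with `age` and `sex`.
#' @param minutes integer minutes to score; default every minute from
#'   `established_at` to the end of the stream.
#' @param width_min,coverage_threshold window parameters as in
#'   [extract_window()].
#' @return data.frame(patient_id, t_min, pain_index); minutes whose window
#'   fails coverage are omitted.
#' @export
pain_index_series <- function(model, stream, baseline, assessments,
                              demographics, minutes = NULL, width_min = 60L,
                              coverage_threshold = 0.90) {
  if (!baseline$established)
    return(data.frame(patient_id = character(0), t_min = integer(0),
                      pain_index = numeric(0)))
  pid <- baseline$patient_id
  series <- stream_to_series(stream)
  tmax <- max(stream$t_min)
  if (is.null(minutes)) minutes <- seq(baseline$established_at, tmax)
  minutes <- minutes[minutes >= baseline$established_at & minutes <= tmax + 1]
  if (!length(minutes))
    return(data.frame(patient_id = character(0), t_min = integer(0),
                      pain_index = numeric(0)))
  rk <- assessments[!is.na(assessments$rass), c("t_min", "rass")]
  rass_at <- function(t) {
    if (!nrow(rk)) return(0L)
    prev <- rk$t_min <= t
    if (any(prev)) rk$rass[max(which(prev))] else rk$rass[which.min(abs(rk$t_min - t))]
  }
  fnames <- feature_names()
  keep <- logical(length(minutes))
  feat_rows <- vector("list", length(minutes))
  for (j in seq_along(minutes)) {
    t <- minutes[j]
    feats <- stats::setNames(numeric(length(fnames)), fnames)
    ok <- TRUE
    for (v in MODEL_VITALS) {
      win <- extract_window(series[[v]], t, baseline$established_at,
                            width_min, coverage_threshold)
      if (!win$ok) { ok <- FALSE; break }
      dv <- deviation_areas(win$values, baseline$baselines[[v]])
      feats[paste0(v, "_value")] <- win$values[length(win$values)]
      feats[paste0(v, "_dev")] <- dv$dev_at_t
      feats[paste0(v, "_area_above")] <- dv$area_above
      feats[paste0(v, "_area_below")] <- dv$area_below
      feats[paste0(v, "_mean_dev")] <- dv$mean_dev
    }
    if (!ok) next
    keep[j] <- TRUE
    feat_rows[[j]] <- c(as.list(feats),
                        list(sex = demographics$sex,
                             age_group = stratify_age(demographics$age),
                             rass = rass_at(t)))
  }
  if (!any(keep))
    return(data.frame(patient_id = character(0), t_min = integer(0),
                      pain_index = numeric(0)))
  fdf <- do.call(rbind.data.frame,
                 c(feat_rows[keep], stringsAsFactors = FALSE))
  data.frame(patient_id = pid, t_min = as.integer(minutes[keep]),
             pain_index = predict_pain_index(model, fdf),
             stringsAsFactors = FALSE)
}

#' @export
print.pain_model <- function(x, ...) {
  cat(sprintf("Pain-index random forest: n_estimators = %d, max_depth = %d\n",
              x$n_estimators, x$max_depth))
  cat(sprintf("  schema: %d predictors; oversampled fraction of training rows: %.2f\n",
              length(x$schema), x$oversample_ratio))
  invisible(x)
}
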