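#' Configuration for a full pipeline run
#'
#' Bundles the per-stage configurations and stage toggles for
#' [run_pipeline()]. All thresholds of the analysis are reachable here.
#'
#' @param generator a [generator_config()].
#' @param rules a [noise_rules()] object.
#' @param stability a [stability_config()].
#' @param model a [model_config()].
#' @param out_dir output directory for stage artifacts (CSV/JSON); `NULL`
#'   keeps everything in memory.
#' @param seed run seed; overrides the generator and model seeds.
#' @param stages named logical toggles over
#'   `simulate, preprocess, baseline, features, train, predict, evaluate,
#'   response`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            rules = noise_rules(),
                            stability = stability_config(),
                            model = model_config(),
                            out_dir = NULL, seed = NULL,
                            stages = c(simulate = TRUE, preprocess = TRUE,
                                       baseline = TRUE, features = TRUE,
                                       train = TRUE, predict = TRUE,
                                       evaluate = TRUE, response = TRUE)) {
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
    model$seed <- as.integer(seed)
  }
  all_stages <- c("simulate", "preprocess", "baseline", "features", "train",
                  "predict", "evaluate", "response")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  structure(list(generator = generator, rules = rules, stability = stability,
                 model = model, out_dir = out_dir, stages = st),
            class = "pipeline_config")
}

#' Run the full pain-index pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess, baseline,
#' features, train, predict (pain index around boluses), evaluate
#' (cross-validated AUROC + operating-point metrics), response (fentanyl
#' trajectory analysis) — and returns a manifest of per-stage row counts,
#' seeds, and output-file hashes. Re-running with an identical configuration
#' reproduces identical artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_run` with `manifest` and the per-stage
#'   results (`cohort`, `filtered`, `baselines`, `features`, `model`,
#'   `pain_index`, `metrics`, `response`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  st <- cfg$stages
  out <- list()
  manifest <- list(seed = cfg$generator$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if (st[["simulate"]]) {
    out$cohort <- stage_guard("simulate", generate_cohort(cfg$generator))
    note("simulate", vitals_rows = nrow(out$cohort$vitals),
         assessments = nrow(out$cohort$assessments),
         boluses = nrow(out$cohort$events),
         positive_rate = mean(out$cohort$assessments$cpot >= 3))
  }
  if (st[["preprocess"]]) {
    if (is.null(out$cohort)) stop("preprocess requires a cohort")
    flt <- stage_guard("preprocess",
                       apply_noise_filter(out$cohort$vitals, cfg$rules))
    out$filtered <- flt$vitals
    out$exclusion_log <- flt$log
    note("preprocess", records_in = nrow(out$cohort$vitals),
         records_excluded = nrow(out$cohort$vitals) - nrow(flt$vitals),
         rules_logged = nrow(flt$log))
  }
  if (st[["baseline"]]) {
    if (is.null(out$filtered)) stop("baseline requires filtered vitals")
    out$baselines <- stage_guard("baseline",
                                 establish_baselines(out$filtered, cfg$stability))
    note("baseline",
         established = sum(out$baselines$baselines$established),
         not_established = sum(!out$baselines$baselines$established))
  }
  if (st[["features"]]) {
    if (is.null(out$baselines)) stop("features requires baselines")
    ft <- stage_guard("features",
                      build_feature_table(out$filtered, out$baselines,
                                          out$cohort$assessments,
                                          out$cohort$demographics))
    out$features <- ft$features
    out$feature_drops <- ft$drops
    note("features", rows = nrow(ft$features), dropped = nrow(ft$drops))
  }
  if (st[["train"]]) {
    if (is.null(out$features)) stop("train requires a feature table")
    out$model <- stage_guard("train",
                             grid_search_train(out$features, cfg$model))
    note("train", n_estimators = out$model$n_estimators,
         max_depth = out$model$max_depth,
         oversample_ratio = out$model$oversample_ratio)
  }
  if (st[["predict"]]) {
    if (is.null(out$model)) stop("predict requires a model")
    out$pain_index <- stage_guard("predict",
                                  cohort_pain_index(out$model, out))
    note("predict", minutes_scored = nrow(out$pain_index))
  }
  if (st[["evaluate"]]) {
    if (is.null(out$model)) stop("evaluate requires a model")
    out$metrics <- stage_guard("evaluate", {
      cv <- repeated_cv_auroc(out$features, cfg$model)
      scores <- predict_pain_index(out$model, out$features)
      conf <- confusion_at_threshold(scores, out$features$label)
      list(cv_auroc_mean = cv$mean, cv_auroc_sd = cv$sd,
           cv_per_repeat = cv$per_repeat,
           leakage_checked = cv$leakage_checked,
           auroc_band = classify_auroc(cv$mean),
           training_confusion = conf,
           harmonic_mean_sens_spec = harmonic_mean_metrics(conf$sensitivity,
                                                           conf$specificity))
    })
    note("evaluate", cv_auroc_mean = out$metrics$cv_auroc_mean,
         auroc_band = out$metrics$auroc_band)
  }
  if (st[["response"]]) {
    if (is.null(out$pain_index)) stop("response requires predicted pain index")
    out$response <- stage_guard("response",
                                fentanyl_response_analysis(out$pain_index,
                                                           out$cohort$events,
                                                           out$cohort$assessments))
    note("response", boluses_analyzed = nrow(out$response$records),
         boluses_dropped = nrow(out$response$dropped))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(out$cohort, cfg$out_dir)
    fw <- function(x, f) if (!is.null(x) && nrow(x))
      data.table::fwrite(x, file.path(cfg$out_dir, f), na = "", quote = FALSE)
    fw(out$exclusion_log, "exclusion_log.csv")
    fw(out$baselines$baselines, "baselines.csv")
    fw(out$features, "features.csv")
    fw(out$pain_index, "painindex.csv")
    if (!is.null(out$response)) {
      fw(out$response$trajectories, "trajectories.csv")
      fw(out$response$records, "response_records.csv")
    }
    files <- list.files(cfg$out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$file_hashes <- as.list(tools::md5sum(files))
    names(manifest$file_hashes) <- basename(files)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$manifest <- manifest
  class(out) <- "pipeline_run"
  out
}

# Per-minute pain index around every bolus (plus at every assessment) for
# the whole cohort; used by the predict stage and the response analysis.
cohort_pain_index <- function(model, out, halfwidth = 60L) {
  cohort <- out$cohort
  res <- list()
  for (pid in unique(cohort$events$patient_id)) {
    b <- out$baselines$objects[[pid]]
    if (is.null(b) || !b$established) next
    ev <- cohort$events[cohort$events$patient_id == pid, , drop = FALSE]
    minutes <- sort(unique(unlist(lapply(ev$t_min, function(t0)
      seq(t0 - halfwidth, t0 + halfwidth)))))
    minutes <- minutes[minutes >= 0]
    res[[pid]] <- pain_index_series(
      model,
      out$filtered[out$filtered$patient_id == pid, , drop = FALSE],
      b,
      cohort$assessments[cohort$assessments$patient_id == pid, , drop = FALSE],
      cohort$demographics[cohort$demographics$patient_id == pid, , drop = FALSE],
      minutes = minutes)
  }
  if (!length(res))
    return(data.frame(patient_id = character(0), t_min = integer(0),
                      pain_index = numeric(0)))
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pain-index pipeline run\n")
  for (s in names(x$manifest$stages)) {
    info <- x$manifest$stages[[s]]
    cat(sprintf("  %-10s %s\n", s,
                paste(names(info), unlist(lapply(info, format)), sep = "=",
                      collapse = "  ")))
  }
  invisible(x)
}
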