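#' Plausibility rules for per-minute vital records
#'
#' Inclusive physiological plausibility ranges plus an optional arterial
#' pressure ordering rule (DBP <= MBP <= SBP when all three are present).
#' A record violating ANY rule in ANY present vital is excluded whole
#' (row-wise exclusion); missing fields alone never trigger exclusion.
#'
#' @param hr,sbp,mbp,dbp,rr,spo2 length-2 numeric `c(lower, upper)` bounds.
#' @param pressure_order enforce DBP <= MBP <= SBP when all three present.
#' @return an object of class `noise_rules`.
#' @export
noise_rules <- function(hr = c(20, 250), sbp = c(30, 300), mbp = c(20, 250),
                        dbp = c(10, 200), rr = c(2, 60), spo2 = c(50, 100),
                        pressure_order = TRUE) {
  ranges <- list(hr = hr, sbp = sbp, mbp = mbp, dbp = dbp, rr = rr, spo2 = spo2)
  for (v in names(ranges)) {
    r <- ranges[[v]]
    if (length(r) != 2 || !is.numeric(r) || r[1] >= r[2])
      stop(sprintf("invalid rule for '%s': need numeric c(lower, upper) with lower < upper", v))
  }
  structure(list(ranges = ranges, pressure_order = isTRUE(pressure_order)),
            class = "noise_rules")
}

read_table_checked <- function(path, schema, numeric_cols, integer_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          na.strings = NULL, data.table = FALSE)
  if (!identical(names(dt), schema))
    stop(sprintf("bad header in %s: expected [%s], found [%s]", path,
                 paste(schema, collapse = ", "), paste(names(dt), collapse = ", ")))
  for (col in numeric_cols) {
    raw <- dt[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   raw[bad[1]], col, bad[1] + 1L, path))
    num[!nzchar(raw)] <- NA_real_
    dt[[col]] <- if (col %in% integer_cols) as.integer(round(num)) else num
  }
  dt
}

#' Read a per-minute vitals table
#'
#' Schema: `patient_id, t_min, hr, sbp, mbp, dbp, rr, spo2` with a mandatory
#' header, empty fields for missing values, and `t_min` in integer minutes
#' since ICU admission (minute 0 = admission). Malformed rows and duplicate
#' (patient, minute) rows are rejected with the offending line cited.
#'
#' @param path CSV file path.
#' @return data.frame ordered by patient and minute.
#' @export
read_vitals <- function(path) {
  schema <- c("patient_id", "t_min", "hr", "sbp", "mbp", "dbp", "rr", "spo2")
  dt <- read_table_checked(path, schema, schema[-1], integer_cols = "t_min")
  if (anyNA(dt$t_min) || any(dt$t_min < 0))
    stop("t_min must be a non-negative integer minute in ", path)
  dup <- duplicated(dt[c("patient_id", "t_min")])
  if (any(dup))
    stop(sprintf("duplicate (patient_id, t_min) row at line %d of %s",
                 which(dup)[1] + 1L, path))
  dt[order(dt$patient_id, dt$t_min), , drop = FALSE]
}

#' Read an assessments table (CPOT/RASS/CAM-ICU)
#'
#' Schema: `patient_id, t_min, cpot, rass, cam_icu`; CPOT in `[0, 8]`,
#' RASS in `[-5, 4]`, `cam_icu` one of `positive`, `negative` or empty.
#'
#' @param path CSV file path.
#' @return data.frame ordered by patient and minute.
#' @export
read_assessments <- function(path) {
  schema <- c("patient_id", "t_min", "cpot", "rass", "cam_icu")
  dt <- read_table_checked(path, schema, c("t_min", "cpot", "rass"),
                           integer_cols = c("t_min", "cpot", "rass"))
  if (any(dt$cpot < 0 | dt$cpot > 8, na.rm = TRUE))
    stop("cpot outside [0, 8] in ", path)
  if (any(dt$rass < -5 | dt$rass > 4, na.rm = TRUE))
    stop("rass outside [-5, 4] in ", path)
  dt$cam_icu[!nzchar(dt$cam_icu)] <- NA_character_
  bad <- which(!is.na(dt$cam_icu) & !dt$cam_icu %in% c("positive", "negative"))
  if (length(bad))
    stop(sprintf("invalid cam_icu value '%s' at line %d of %s",
                 dt$cam_icu[bad[1]], bad[1] + 1L, path))
  dt[order(dt$patient_id, dt$t_min), , drop = FALSE]
}

#' Read an analgesic bolus events table
#'
#' Schema: `patient_id, t_min, drug, dose_ug`.
#'
#' @param path CSV file path.
#' @return data.frame ordered by patient and minute.
#' @export
read_events <- function(path) {
  schema <- c("patient_id", "t_min", "drug", "dose_ug")
  dt <- read_table_checked(path, schema, c("t_min", "dose_ug"),
                           integer_cols = "t_min")
  dt[order(dt$patient_id, dt$t_min), , drop = FALSE]
}

#' Write cohort tables to a directory
#'
#' Writes `vitals.csv`, `assessments.csv`, `events.csv` and, when ground
#' truth is available, `ground_truth.csv` (true per-vital baselines and
#' demographics) plus `ground_truth_boluses.csv` (responder flags).
#'
#' @param cohort an `icu_cohort` from [generate_cohort()], or a list with
#'   `vitals`, `assessments`, `events` data.frames.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), na = "",
                                          quote = FALSE)
  fw(cohort$vitals, "vitals.csv")
  fw(cohort$assessments, "assessments.csv")
  fw(cohort$events, "events.csv")
  if (!is.null(cohort$ground_truth)) {
    gt <- merge(cohort$ground_truth$true_baselines, cohort$demographics,
                by = "patient_id", suffixes = c("", "_demo"))
    fw(gt, "ground_truth.csv")
    fw(cohort$ground_truth$boluses, "ground_truth_boluses.csv")
  }
  invisible(dir)
}

#' Remove implausible per-minute records (row-wise exclusion)
#'
#' Applies the plausibility [noise_rules()] to a vitals table: any record in
#' which any present vital violates any rule is removed whole, and the
#' exclusion log records every violated rule for that minute. Surviving
#' records are returned unmodified, so filtering is idempotent.
#'
#' @param vitals data.frame with the vitals schema (one or many patients).
#' @param rules a [noise_rules()] object.
#' @return list with `vitals` (surviving records) and `log`
#'   (data.frame patient_id, t_min, rule).
#' @export
apply_noise_filter <- function(vitals, rules = noise_rules()) {
  stopifnot(inherits(rules, "noise_rules"))
  viol <- list()
  bad <- rep(FALSE, nrow(vitals))
  for (v in names(rules$ranges)) {
    r <- rules$ranges[[v]]
    x <- vitals[[v]]
    hit <- !is.na(x) & (x < r[1] | x > r[2])
    if (any(hit)) {
      viol[[length(viol) + 1]] <- data.frame(
        patient_id = vitals$patient_id[hit], t_min = vitals$t_min[hit],
        rule = paste0(v, "_range"), stringsAsFactors = FALSE)
      bad <- bad | hit
    }
  }
  if (rules$pressure_order) {
    p <- !is.na(vitals$sbp) & !is.na(vitals$mbp) & !is.na(vitals$dbp)
    hit <- p & !(vitals$dbp <= vitals$mbp & vitals$mbp <= vitals$sbp)
    if (any(hit)) {
      viol[[length(viol) + 1]] <- data.frame(
        patient_id = vitals$patient_id[hit], t_min = vitals$t_min[hit],
        rule = "pressure_order", stringsAsFactors = FALSE)
      bad <- bad | hit
    }
  }
  log <- if (length(viol)) do.call(rbind, viol) else
    data.frame(patient_id = character(0), t_min = integer(0),
               rule = character(0), stringsAsFactors = FALSE)
  log <- log[order(log$patient_id, log$t_min, log$rule), , drop = FALSE]
  rownames(log) <- NULL
  out <- vitals[!bad, , drop = FALSE]
  rownames(out) <- NULL
  list(vitals = out, log = log)
}
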