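#' Patient-level cohort tables and longitudinal RDW series
#'
#' A cohort table holds one row per ARDS patient with the covariates used by
#' the mortality models (age, sex, comorbidity-count category, SOFA score,
#' PaO2/FiO2 ratio, baseline RDW) and the three nested mortality outcomes
#' (ICU, in-hospital, 90-day).  A long RDW table holds one row per RDW
#' measurement (patient id, days since ARDS diagnosis, RDW percent).
#'
#' @name cohort-data
NULL

COHORT_COLUMNS <- c("patient_id", "age", "sex", "comorbidity_category",
                    "sofa", "pf_ratio", "rdw_baseline",
                    "icu_death", "hosp_death", "death_90d")

RDW_LONG_COLUMNS <- c("patient_id", "time_days", "rdw")

COMORBIDITY_LEVELS <- c("0", "1", "2", "3plus")

#' Validate a patient-level cohort table
#'
#' Checks the schema and every row-level invariant: age >= 18, SOFA in
#' 0..24, PaO2/FiO2 and RDW strictly positive, sex in \{male, female\},
#' comorbidity category in \{0, 1, 2, 3plus\}, unique patient ids, and the
#' outcome nesting ICU death => in-hospital death => 90-day death.  Outcome
#' columns given as 0/1 are converted to logical; no other coercion is
#' performed, and any missing required value is an error (complete-case
#' contract).
#'
#' @param cohort A data frame with the columns listed in Details.
#' @return The validated cohort as a `data.frame` (invisibly identical to
#'   the input up to outcome type normalisation).
#' @details Required columns: `patient_id`, `age`, `sex`,
#'   `comorbidity_category`, `sofa`, `pf_ratio`, `rdw_baseline`,
#'   `icu_death`, `hosp_death`, `death_90d`.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop_schema("cohort must be a data frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0L)
    stop_schema("cohort is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  cohort <- as.data.frame(cohort)[COHORT_COLUMNS]
  n <- nrow(cohort)

  cohort$patient_id <- as.character(cohort$patient_id)
  cohort$comorbidity_category <- as.character(cohort$comorbidity_category)
  for (col in c("icu_death", "hosp_death", "death_90d")) {
    x <- cohort[[col]]
    if (is.numeric(x)) {
      if (any(!is.na(x) & !(x %in% c(0, 1))))
        stop_validation("row %d, field %s: outcome flags must be 0/1 or logical",
                        which(!is.na(x) & !(x %in% c(0, 1)))[1L], col)
      x <- x == 1
    }
    if (!is.logical(x))
      stop_validation("field %s: outcome flags must be 0/1 or logical", col)
    cohort[[col]] <- x
  }

  check_row <- function(ok, field, what) {
    bad <- which(!ok)
    if (length(bad) > 0L)
      stop_validation("row %d, field %s: %s", bad[1L], field, what)
  }
  for (col in COHORT_COLUMNS)
    check_row(!is.na(cohort[[col]]), col, "missing value (complete cases required)")

  if (anyDuplicated(cohort$patient_id))
    stop_validation("row %d, field patient_id: duplicate id '%s'",
                    anyDuplicated(cohort$patient_id),
                    cohort$patient_id[anyDuplicated(cohort$patient_id)])
  check_row(is.numeric(cohort$age) & cohort$age >= 18, "age",
            "must be numeric and >= 18 years")
  check_row(cohort$sex %in% c("male", "female"), "sex",
            "must be 'male' or 'female'")
  check_row(cohort$comorbidity_category %in% COMORBIDITY_LEVELS,
            "comorbidity_category", "must be one of 0, 1, 2, 3plus")
  check_row(is.numeric(cohort$sofa) & cohort$sofa >= 0 & cohort$sofa <= 24 &
              cohort$sofa == round(cohort$sofa), "sofa",
            "must be an integer score in 0..24")
  check_row(is.numeric(cohort$pf_ratio) & cohort$pf_ratio > 0, "pf_ratio",
            "must be a positive PaO2/FiO2 ratio (mmHg)")
  check_row(is.numeric(cohort$rdw_baseline) & cohort$rdw_baseline > 0,
            "rdw_baseline", "must be a positive RDW percent")
  check_row(!(cohort$icu_death & !cohort$hosp_death), "hosp_death",
            "outcome nesting violated: ICU death implies in-hospital death")
  check_row(!(cohort$hosp_death & !cohort$death_90d), "death_90d",
            "outcome nesting violated: in-hospital death implies 90-day death")
  cohort
}

#' Read and validate a cohort CSV
#'
#' @param path Path to a comma-separated, UTF-8, header-first CSV with the
#'   cohort columns (outcome flags coded 0/1).
#' @return A validated cohort `data.frame`.
#' @seealso [validate_cohort()] for the schema, [write_cohort()] for the
#'   inverse operation.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_schema("cohort file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(raw)
}

#' Write a cohort table to CSV
#'
#' Outcome flags are written as 0/1 so the file round-trips through
#' [read_cohort()].
#'
#' @param cohort A validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  for (col in c("icu_death", "hosp_death", "death_90d"))
    out[[col]] <- as.integer(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a long-format RDW measurement table
#'
#' One row per measurement with columns `patient_id`, `time_days` (days
#' since ARDS diagnosis, >= 0) and `rdw` (percent, > 0).  Duplicate
#' (patient, time) pairs are rejected; rows are returned sorted by patient
#' (first appearance order) and time.
#'
#' @param rdw_long A data frame in long format.
#' @return The validated, sorted `data.frame`.
#' @export
validate_rdw_long <- function(rdw_long) {
  if (!is.data.frame(rdw_long)) stop_schema("rdw_long must be a data frame")
  missing_cols <- setdiff(RDW_LONG_COLUMNS, names(rdw_long))
  if (length(missing_cols) > 0L)
    stop_schema("rdw table is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  rdw_long <- as.data.frame(rdw_long)[RDW_LONG_COLUMNS]
  rdw_long$patient_id <- as.character(rdw_long$patient_id)
  for (col in RDW_LONG_COLUMNS) {
    bad <- which(is.na(rdw_long[[col]]))
    if (length(bad) > 0L)
      stop_validation("row %d, field %s: missing value", bad[1L], col)
  }
  bad <- which(!(is.numeric(rdw_long$time_days) & rdw_long$time_days >= 0))
  if (length(bad) > 0L)
    stop_validation("row %d, field time_days: must be >= 0 days", bad[1L])
  bad <- which(!(is.numeric(rdw_long$rdw) & rdw_long$rdw > 0))
  if (length(bad) > 0L)
    stop_validation("row %d, field rdw: must be a positive percent", bad[1L])
  key <- paste(rdw_long$patient_id, rdw_long$time_days, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup > 0L)
    stop_validation("row %d, field time_days: duplicate measurement time %g for patient '%s'",
                    dup, rdw_long$time_days[dup], rdw_long$patient_id[dup])
  ord <- order(match(rdw_long$patient_id, unique(rdw_long$patient_id)),
               rdw_long$time_days)
  out <- rdw_long[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and validate a long-format RDW CSV
#'
#' @param path Path to a CSV with columns `patient_id`, `time_days`, `rdw`.
#' @return A validated `data.frame`, sorted within patient by time.
#' @export
read_rdw_long <- function(path) {
  if (!file.exists(path)) stop_schema("rdw file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character"))
  validate_rdw_long(raw)
}

#' Write a long-format RDW table to CSV
#'
#' @param rdw_long A validated long RDW data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdw_long <- function(rdw_long, path) {
  rdw_long <- validate_rdw_long(rdw_long)
  write.csv(rdw_long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a long RDW table into per-patient series
#'
#' @param rdw_long A validated long RDW data frame.
#' @return A named list of data frames (`time_days`, `rdw`), one per
#'   patient, observations sorted by time.
#' @export
rdw_series_split <- function(rdw_long) {
  rdw_long <- validate_rdw_long(rdw_long)
  ids <- unique(rdw_long$patient_id)
  out <- split(rdw_long[c("time_days", "rdw")], factor(rdw_long$patient_id, levels = ids))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
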