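#' Assemble and validate a longitudinal CRP cohort
#'
#' A cohort bundles one row per patient of covariates with a long-format
#' table of C-reactive protein (CRP) measurements taken relative to the day
#' of surgery (day 0 = operation day, negative days preoperative).
#'
#' @param patients A data frame with one row per patient and columns
#'   `patient_id`, `age` (years), `sex` (1 = male, 2 = female), `bmi`
#'   (kg/m^2), `approach` (surgical approach code 1-6: 1 anterolateral
#'   Watson-Jones, 2 posterior, 3 lateral Bauer, 4 anterior intrapelvic
#'   STOPPA, 5 Kocher-Langenbeck, 6 anterior), `indication_trauma` (logical),
#'   `days_until_surgery`, `postop_days_in_hospital`, `infection` (logical)
#'   and optionally `organism`.
#' @param series A data frame with columns `patient_id`, `day` (integer day
#'   relative to surgery) and `crp_mg_L` (CRP concentration, mg/L).
#'
#' @return An object of class `crp_cohort`: a list with tibbles `patients`
#'   and `series`, the latter sorted by `(patient_id, day)`.
#'
#' @details Validation enforces the domain constraints of the study
#'   population: adults only (`age > 18`), positive BMI, sex codes in
#'   \{1, 2\}, approach codes in \{1, ..., 6\}, non-negative CRP, no
#'   duplicated `(patient_id, day)` rows, and a one-to-one match between
#'   patients and their measurement series.
#'
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = "p1", age = 70, sex = 1, bmi = 26, approach = 1,
#'   indication_trauma = FALSE, days_until_surgery = 1,
#'   postop_days_in_hospital = 10, infection = FALSE, organism = NA_character_
#' )
#' ser <- tibble::tibble(patient_id = "p1", day = c(-1, 1, 3), crp_mg_L = c(5, 80, 120))
#' crp_cohort(pts, ser)
#' @export
crp_cohort <- function(patients, series) {
  patients <- tibble::as_tibble(patients)
  series <- tibble::as_tibble(series)
  req_pat <- c(
    "patient_id", "age", "sex", "bmi", "approach", "indication_trauma",
    "days_until_surgery", "postop_days_in_hospital", "infection"
  )
  miss <- setdiff(req_pat, names(patients))
  if (length(miss) > 0) {
    stop("patients table is missing columns: ", paste(miss, collapse = ", "))
  }
  req_ser <- c("patient_id", "day", "crp_mg_L")
  miss <- setdiff(req_ser, names(series))
  if (length(miss) > 0) {
    stop("series table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"organism" %in% names(patients)) patients$organism <- NA_character_

  if (anyDuplicated(patients$patient_id) > 0) {
    stop("duplicate patient_id in patients table")
  }
  if (nrow(patients) > 0) {
    if (!all(patients$sex %in% c(1, 2))) stop("sex code outside {1, 2}")
    if (!all(patients$approach %in% 1:6)) stop("approach code outside 1..6")
    if (!all(patients$bmi > 0)) stop("bmi must be positive")
    if (!all(patients$age > 18)) stop("age must exceed 18 years")
    patients$indication_trauma <- as.logical(patients$indication_trauma)
    patients$infection <- as.logical(patients$infection)
  }
  if (nrow(series) > 0) {
    if (!all(is.finite(series$day))) stop("non-finite measurement day")
    if (!all(series$crp_mg_L >= 0)) stop("negative CRP value")
    if (anyDuplicated(series[, c("patient_id", "day")]) > 0) {
      stop("duplicate (patient_id, day) measurement rows")
    }
  }
  only_pat <- setdiff(patients$patient_id, series$patient_id)
  only_ser <- setdiff(series$patient_id, patients$patient_id)
  if (length(only_pat) > 0) {
    stop("patients without any CRP series: ", paste(only_pat, collapse = ", "))
  }
  if (length(only_ser) > 0) {
    stop("CRP series without a patient record: ", paste(only_ser, collapse = ", "))
  }
  series <- dplyr::arrange(series, .data$patient_id, .data$day)
  structure(list(patients = patients, series = series), class = "crp_cohort")
}

#' @export
print.crp_cohort <- function(x, ...) {
  cat(
    "<crp_cohort> ", nrow(x$patients), " patients, ",
    nrow(x$series), " CRP measurements, ",
    sum(x$patients$infection), " infected\n",
    sep = ""
  )
  invisible(x)
}

#' Read a cohort from its two CSV files
#'
#' @param series_path Path to the measurement CSV with header
#'   `patient_id,day,crp_mg_L`.
#' @param patients_path Path to the covariate CSV with header
#'   `patient_id,age,sex,bmi,approach,indication_trauma,days_until_surgery,postop_days_in_hospital,infection,organism`.
#'   Logical columns are serialized as 0/1.
#'
#' @return A validated [crp_cohort()]; series rows sorted by
#'   `(patient_id, day)` regardless of file order.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(series_path, patients_path) {
  series <- readr::read_csv(series_path, show_col_types = FALSE)
  patients <- readr::read_csv(patients_path, show_col_types = FALSE)
  if ("indication_trauma" %in% names(patients)) {
    patients$indication_trauma <- as.logical(patients$indication_trauma)
  }
  if ("infection" %in% names(patients)) {
    patients$infection <- as.logical(patients$infection)
  }
  if ("organism" %in% names(patients)) {
    patients$organism <- as.character(patients$organism)
  }
  if ("patient_id" %in% names(patients)) {
    patients$patient_id <- as.character(patients$patient_id)
  }
  if ("patient_id" %in% names(series)) {
    series$patient_id <- as.character(series$patient_id)
  }
  crp_cohort(patients, series)
}

#' Write a cohort to its two CSV files
#'
#' Logical covariates are serialized as 0/1 so that
#' `read_cohort(write_cohort(...))` round-trips exactly.
#'
#' @param cohort A [crp_cohort()].
#' @param series_path,patients_path Output file paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, series_path, patients_path) {
  stopifnot(inherits(cohort, "crp_cohort"))
  pats <- cohort$patients
  pats$indication_trauma <- as.integer(pats$indication_trauma)
  pats$infection <- as.integer(pats$infection)
  readr::write_csv(cohort$series, series_path)
  readr::write_csv(pats, patients_path)
  invisible(cohort)
}

#' Restrict a CRP series to the postoperative course
#'
#' Keeps measurements with `day >= 1`. Day 0 is the operation day and is
#' excluded to avoid mixing samples drawn before and after the procedure on
#' the same calendar day; preoperative days are excluded by definition.
#'
#' @param series A data frame with at least columns `day` and `crp_mg_L`
#'   (one patient's measurements).
#' @return The same data frame filtered to `day >= 1` (possibly empty).
#' @export
postoperative_subseries <- function(series) {
  series[series$day >= 1, , drop = FALSE]
}

#' Extract one patient's series from a cohort
#'
#' @param cohort A [crp_cohort()].
#' @param patient_id Identifier present in the cohort.
#' @return A tibble with columns `day`, `crp_mg_L`, sorted by day.
#' @export
patient_series <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "crp_cohort"))
  out <- cohort$series[cohort$series$patient_id == patient_id, c("day", "crp_mg_L")]
  if (nrow(out) == 0) stop("unknown patient_id: ", patient_id)
  out
}
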