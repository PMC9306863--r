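#' Assemble a validated asthma cohort
#'
#' Bundles the three tables the pipeline operates on: one row per patient
#' of clinical features, a long table of dated blood eosinophil count
#' (BEC) observations, and optionally one induced-sputum differential per
#' patient. All validation happens here so downstream stages can assume
#' clean inputs.
#'
#' @param patients Tibble with columns `patient_id`, `enrolment_date`
#'   (Date), `on_anti_il5`, `maintenance_ocs`, `nasal_polyps` (logical),
#'   `feno_ppb`, `age_at_diagnosis` (numeric, may be `NA`),
#'   `age_at_enrolment` (numeric).
#' @param bec Tibble with columns `patient_id`, `obs_date` (Date),
#'   `count` (non-negative, cells/uL).
#' @param sputum Optional tibble with columns `patient_id`, `eos_pct`,
#'   `neut_pct` (percent of non-squamous cells).
#' @return An object of class `eos_cohort`: a list with elements
#'   `patients`, `bec`, `sputum`.
#' @examples
#' patients <- tibble::tibble(
#'   patient_id = "P1", enrolment_date = as.Date("2020-01-01"),
#'   on_anti_il5 = FALSE, maintenance_ocs = FALSE, nasal_polyps = TRUE,
#'   feno_ppb = 30, age_at_diagnosis = 25, age_at_enrolment = 50
#' )
#' bec <- tibble::tibble(
#'   patient_id = "P1", obs_date = as.Date("2019-06-01"), count = 200L
#' )
#' eos_cohort(patients, bec)
#' @export
eos_cohort <- function(patients, bec, sputum = NULL) {
  patients <- validate_patients(patients)
  bec <- validate_bec(bec)
  if (!is.null(sputum)) sputum <- validate_sputum(sputum)

  orphan <- setdiff(bec$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    rlang::abort(
      sprintf("BEC observations refer to %d patient id(s) absent from the patient table (e.g. %s).",
              length(orphan), orphan[1]),
      class = "eosgradient_validation_error"
    )
  }
  structure(list(patients = patients, bec = bec, sputum = sputum),
            class = "eos_cohort")
}

#' @export
print.eos_cohort <- function(x, ...) {
  cat(sprintf("<eos_cohort> %d patients, %d BEC observations%s\n",
              nrow(x$patients), nrow(x$bec),
              if (is.null(x$sputum)) "" else
                sprintf(", %d sputum differentials", nrow(x$sputum))))
  invisible(x)
}

required_patient_cols <- c(
  "patient_id", "enrolment_date", "on_anti_il5", "maintenance_ocs",
  "nasal_polyps", "feno_ppb", "age_at_diagnosis", "age_at_enrolment"
)

abort_missing_cols <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("%s table is missing required column(s): %s.",
              table, paste(missing, collapse = ", ")),
      class = "eosgradient_schema_error"
    )
  }
}

#' Validate a patient feature table
#'
#' Checks column presence, types, uniqueness of `patient_id`, and the
#' record-level invariants: non-negative FeNO and ages, and
#' `age_at_diagnosis <= age_at_enrolment` when both are present.
#' `feno_ppb` and `age_at_diagnosis` may be missing (resolved later by
#' [derive_flags()]); everything else must be complete.
#'
#' @param patients A data frame of patient records.
#' @return The validated tibble (invisibly coerced to tibble).
#' @export
validate_patients <- function(patients) {
  abort_missing_cols(patients, required_patient_cols, "patient")
  patients <- tibble::as_tibble(patients)
  if (anyNA(patients$patient_id)) {
    rlang::abort("`patient_id` must not be missing.",
                 class = "eosgradient_validation_error")
  }
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1]
    rlang::abort(sprintf("Duplicate patient_id in patient table: %s.", dup),
                 class = "eosgradient_validation_error")
  }
  if (!inherits(patients$enrolment_date, "Date") || anyNA(patients$enrolment_date)) {
    rlang::abort("`enrolment_date` must be a complete Date column.",
                 class = "eosgradient_validation_error")
  }
  for (col in c("on_anti_il5", "maintenance_ocs", "nasal_polyps")) {
    v <- patients[[col]]
    if (!is.logical(v) || anyNA(v)) {
      rlang::abort(sprintf("`%s` must be logical with no missing values.", col),
                   class = "eosgradient_validation_error")
    }
  }
  if (any(patients$feno_ppb < 0, na.rm = TRUE)) {
    rlang::abort("`feno_ppb` must be non-negative where present.",
                 class = "eosgradient_validation_error")
  }
  if (anyNA(patients$age_at_enrolment) || any(patients$age_at_enrolment < 0)) {
    rlang::abort("`age_at_enrolment` must be complete and non-negative.",
                 class = "eosgradient_validation_error")
  }
  if (any(patients$age_at_diagnosis < 0, na.rm = TRUE)) {
    rlang::abort("`age_at_diagnosis` must be non-negative where present.",
                 class = "eosgradient_validation_error")
  }
  bad <- which(!is.na(patients$age_at_diagnosis) &
                 patients$age_at_diagnosis > patients$age_at_enrolment)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("age_at_diagnosis exceeds age_at_enrolment for patient %s.",
              patients$patient_id[bad[1]]),
      class = "eosgradient_validation_error"
    )
  }
  patients
}

#' Validate a blood eosinophil observation table
#'
#' @param bec A data frame with `patient_id`, `obs_date`, `count`.
#' @return The validated tibble.
#' @export
validate_bec <- function(bec) {
  abort_missing_cols(bec, c("patient_id", "obs_date", "count"), "BEC")
  bec <- tibble::as_tibble(bec)
  if (anyNA(bec$patient_id)) {
    rlang::abort("BEC `patient_id` must not be missing.",
                 class = "eosgradient_validation_error")
  }
  if (!inherits(bec$obs_date, "Date") || anyNA(bec$obs_date)) {
    rlang::abort("BEC `obs_date` must be a complete Date column.",
                 class = "eosgradient_validation_error")
  }
  if (anyNA(bec$count) || any(bec$count < 0)) {
    rlang::abort("BEC `count` must be complete and non-negative (cells/uL).",
                 class = "eosgradient_validation_error")
  }
  bec
}

#' Validate a sputum differential table
#'
#' Percentages are of non-squamous cells; each must lie in \[0, 100\] and
#' eosinophil plus neutrophil percentages cannot exceed 100.
#'
#' @param sputum A data frame with `patient_id`, `eos_pct`, `neut_pct`.
#' @return The validated tibble.
#' @export
validate_sputum <- function(sputum) {
  abort_missing_cols(sputum, c("patient_id", "eos_pct", "neut_pct"), "sputum")
  sputum <- tibble::as_tibble(sputum)
  if (anyNA(sputum$patient_id)) {
    rlang::abort("Sputum `patient_id` must not be missing.",
                 class = "eosgradient_validation_error")
  }
  if (anyDuplicated(sputum$patient_id)) {
    rlang::abort("Sputum table must have at most one differential per patient.",
                 class = "eosgradient_validation_error")
  }
  for (col in c("eos_pct", "neut_pct")) {
    v <- sputum[[col]]
    if (anyNA(v) || any(v < 0) || any(v > 100)) {
      rlang::abort(sprintf("`%s` must be complete and within [0, 100].", col),
                   class = "eosgradient_validation_error")
    }
  }
  if (any(sputum$eos_pct + sputum$neut_pct > 100)) {
    bad <- sputum$patient_id[which(sputum$eos_pct + sputum$neut_pct > 100)][1]
    rlang::abort(
      sprintf("eos_pct + neut_pct exceeds 100 for patient %s.", bad),
      class = "eosgradient_validation_error"
    )
  }
  sputum
}
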