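#' Derive binary type-2 feature flags from patient records
#'
#' Resolves the raw clinical features into the five booleans the decision
#' table consumes: nasal polyps, elevated FeNO, adult-onset asthma,
#' maintenance oral corticosteroids, and anti-IL-5/anti-IL-5R-alpha
#' therapy. FeNO elevation is strict (`feno_ppb > feno_cut`); adult onset
#' is `age_at_diagnosis >= adult_onset_age`. Missing FeNO or missing
#' diagnosis age resolve conservatively to `FALSE` — a type-2 feature is
#' never claimed without evidence — and each resolution is reported.
#'
#' @param patients A validated patient table (see [validate_patients()]),
#'   or a single-patient one-row data frame.
#' @param thresholds A [grading_thresholds()] object.
#' @param quiet If `FALSE` (default), emit one message summarising any
#'   missing-data resolutions.
#' @return A tibble with `patient_id` and logical columns `nasal_polyps`,
#'   `feno_elevated`, `adult_onset`, `maintenance_ocs`, `on_anti_il5`.
#'   The attribute `"resolutions"` holds a tibble (`patient_id`, `field`)
#'   recording every missing value resolved to `FALSE`.
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = c("A", "B"), enrolment_date = as.Date("2020-01-01"),
#'   on_anti_il5 = FALSE, maintenance_ocs = FALSE, nasal_polyps = FALSE,
#'   feno_ppb = c(26, NA), age_at_diagnosis = c(21.5, NA),
#'   age_at_enrolment = 55
#' )
#' derive_flags(pts, quiet = TRUE)
#' @export
derive_flags <- function(patients, thresholds = grading_thresholds(),
                         quiet = FALSE) {
  stopifnot(inherits(thresholds, "grading_thresholds"))
  patients <- validate_patients(patients)

  flags <- tibble::tibble(
    patient_id = patients$patient_id,
    nasal_polyps = patients$nasal_polyps,
    feno_elevated = !is.na(patients$feno_ppb) &
      patients$feno_ppb > thresholds$feno_cut,
    adult_onset = !is.na(patients$age_at_diagnosis) &
      patients$age_at_diagnosis >= thresholds$adult_onset_age,
    maintenance_ocs = patients$maintenance_ocs,
    on_anti_il5 = patients$on_anti_il5
  )

  resolutions <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = patients$patient_id[is.na(patients$feno_ppb)],
      field = "feno_ppb"
    ),
    tibble::tibble(
      patient_id = patients$patient_id[is.na(patients$age_at_diagnosis)],
      field = "age_at_diagnosis"
    )
  )
  attr(flags, "resolutions") <- resolutions
  if (!quiet && nrow(resolutions) > 0) {
    rlang::inform(sprintf(
      "derive_flags: %d missing value(s) resolved to FALSE (%s).",
      nrow(resolutions),
      paste(sprintf("%s:%s", resolutions$patient_id, resolutions$field),
            collapse = ", ")
    ))
  }
  flags
}
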