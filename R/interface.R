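#' Read a cohort from CSV files
#'
#' Loads and validates the three pipeline inputs. Expected schemas
#' (RFC-4180 CSV, ISO-8601 dates, booleans as `true`/`false`, blanks as
#' missing):
#' * `cohort_csv`: `patient_id, enrolment_date, on_anti_il5,
#'   maintenance_ocs, nasal_polyps, feno_ppb, age_at_diagnosis,
#'   age_at_enrolment`
#' * `bec_csv`: `patient_id, obs_date, count`
#' * `sputum_csv` (optional): `patient_id, eos_pct, neut_pct`
#'
#' Schema violations are reported with the offending column and row
#' numbers; duplicate `(patient_id, obs_date, count)` BEC triples are
#' rejected as double entries; a missing `patient_id` anywhere is a hard
#' failure.
#'
#' @param cohort_csv,bec_csv Paths to the patient and BEC tables.
#' @param sputum_csv Optional path to the sputum differential table.
#' @param quiet If `FALSE` (default), report blank-field resolutions.
#' @return An [eos_cohort()].
#' @export
read_cohort <- function(cohort_csv, bec_csv, sputum_csv = NULL,
                        quiet = FALSE) {
  patients <- read_checked(
    cohort_csv, "patient", required_patient_cols,
    readr::cols(
      patient_id = readr::col_character(),
      enrolment_date = readr::col_date(),
      on_anti_il5 = readr::col_logical(),
      maintenance_ocs = readr::col_logical(),
      nasal_polyps = readr::col_logical(),
      feno_ppb = readr::col_double(),
      age_at_diagnosis = readr::col_double(),
      age_at_enrolment = readr::col_double()
    )
  )
  bec <- read_checked(
    bec_csv, "BEC", c("patient_id", "obs_date", "count"),
    readr::cols(
      patient_id = readr::col_character(),
      obs_date = readr::col_date(),
      count = readr::col_integer()
    )
  )
  dup <- duplicated(bec[c("patient_id", "obs_date", "count")])
  if (any(dup)) {
    rows <- utils::head(which(dup), 5)
    rlang::abort(
      sprintf("Duplicate (patient_id, obs_date, count) BEC rows at line(s) %s of %s.",
              paste(rows + 1L, collapse = ", "), bec_csv),
      class = "eosgradient_schema_error"
    )
  }
  sputum <- NULL
  if (!is.null(sputum_csv)) {
    sputum <- read_checked(
      sputum_csv, "sputum", c("patient_id", "eos_pct", "neut_pct"),
      readr::cols(
        patient_id = readr::col_character(),
        eos_pct = readr::col_double(),
        neut_pct = readr::col_double()
      )
    )
  }
  if (!quiet) {
    n_blank <- sum(is.na(patients$feno_ppb)) +
      sum(is.na(patients$age_at_diagnosis))
    if (n_blank > 0) {
      rlang::inform(sprintf(
        "read_cohort: %d blank feno_ppb/age_at_diagnosis field(s) read as missing.",
        n_blank
      ))
    }
  }
  eos_cohort(patients, bec, sputum)
}

# Shared CSV reader: checks the file exists, the header is complete, and
# every field parses under the declared column types; parse failures are
# reported with 1-based data-row numbers.
read_checked <- function(path, table, required, col_types) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("%s file not found: %s", table, path),
                 class = "eosgradient_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("%s table %s is missing required column(s): %s.",
              table, path, paste(missing, collapse = ", ")),
      class = "eosgradient_schema_error"
    )
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    shown <- utils::head(probs, 5)
    rlang::abort(
      paste0(
        sprintf("%s table %s has %d unparsable field(s):\n", table, path,
                nrow(probs)),
        paste(sprintf("  line %d, column %s: expected %s, got \"%s\"",
                      shown$row, header[shown$col], shown$expected,
                      shown$actual),
              collapse = "\n")
      ),
      class = "eosgradient_schema_error"
    )
  }
  if ("patient_id" %in% names(df) && anyNA(df$patient_id)) {
    rlang::abort(
      sprintf("%s table %s has missing patient_id at data row(s) %s.",
              table, path,
              paste(utils::head(which(is.na(df$patient_id)), 5),
                    collapse = ", ")),
      class = "eosgradient_schema_error"
    )
  }
  df
}

#' Write grading reports to a directory
#'
#' Emits the standard result files for one pipeline run: per-patient
#' grade assignments, the per-criterion count table, the per-grade
#' distribution, optionally the grade-by-sputum cross-tabulation, and a
#' short human-readable summary. Numeric formatting follows the
#' summarisation conventions (table percentages to one decimal place,
#' discordance statistics to whole percent).
#'
#' @param grading A [grade_cohort()] result.
#' @param out_dir Output directory; created if absent.
#' @param crosstab Optional [cross_tabulate()] result.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(grading, out_dir, crosstab = NULL) {
  stopifnot(inherits(grading, "cohort_grading"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    rlang::abort(sprintf("Cannot write to directory: %s", out_dir),
                 class = "eosgradient_io_error")
  }
  wlab <- format_window(grading$window)
  paths <- c(
    assignments = file.path(out_dir, "grade_assignments.csv"),
    criterion_counts = file.path(out_dir,
                                 sprintf("criterion_counts_%s.csv", wlab)),
    distribution = file.path(out_dir,
                             sprintf("grade_distribution_%s.csv", wlab)),
    summary = file.path(out_dir, "summary.txt")
  )
  readr::write_csv(grading$assignments, paths[["assignments"]])
  readr::write_csv(tibble::as_tibble(grading$criterion_counts),
                   paths[["criterion_counts"]])
  dist <- grade_distribution(grading$criterion_counts)
  readr::write_csv(dist, paths[["distribution"]])

  lines <- c(
    sprintf("Eosinophil gradient grading — window: %s", wlab),
    sprintf("Patients graded: %d (ungradable: %d)",
            sum(grading$criterion_counts$count),
            attr(grading$criterion_counts, "ungradable")),
    sprintf("  Grade %d: %d (%.1f%%)", dist$grade, dist$count, dist$pct)
  )
  if (!is.null(crosstab)) {
    paths <- c(paths, crosstab = file.path(out_dir, "sputum_crosstab.csv"))
    ct <- tibble::as_tibble(unclass_crosstab(crosstab), rownames = "grade")
    readr::write_csv(ct, paths[["crosstab"]])
    ds <- discordance_stats(crosstab)
    lines <- c(
      lines,
      sprintf("Sputum-paired patients: %d", attr(crosstab, "n")),
      sprintf("Grade-3 without sputum eosinophilia: %d%%",
              ds$grade3_without_sputum_eosinophilia_pct),
      sprintf("Mixed granular among sputum-eosinophilic: %d%%",
              ds$neutrophilic_among_sputum_eosinophilic_pct)
    )
  }
  writeLines(lines, paths[["summary"]])
  invisible(paths)
}
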