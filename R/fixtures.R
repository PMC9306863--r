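#' Published WATCH per-criterion grading counts
#'
#' The per-criterion patient counts reported for the WATCH
#' difficult-asthma cohort under each of the four blood eosinophil
#' observation windows (latest pre-enrolment result, highest in the last
#' 5 years, highest in the last 10 years, highest ever). Each column sums
#' to the 500 graded patients. These counts, together with
#' [fixture_from_criterion_counts()], let every downstream stage be
#' exercised end-to-end without access to the underlying registry data.
#'
#' @param column One of `"latest"`, `"5y"`, `"10y"`, `"ever"`; `NULL`
#'   (default) returns all four columns.
#' @return A tibble with a `criterion` factor column and one integer
#'   column per requested window.
#' @examples
#' watch_table1_counts("ever")
#' @export
watch_table1_counts <- function(column = NULL) {
  tab <- tibble::tibble(
    criterion = factor(criterion_levels, levels = criterion_levels),
    latest = c(163L, 39L, 15L, 8L, 28L, 28L, 71L, 82L, 66L),
    `5y`   = c(296L, 15L, 19L, 5L, 29L, 27L, 33L, 39L, 37L),
    `10y`  = c(342L, 10L, 18L, 4L, 29L, 29L, 22L, 25L, 21L),
    ever   = c(359L,  8L, 17L, 3L, 25L, 25L, 20L, 22L, 21L)
  )
  if (is.null(column)) return(tab)
  column <- match.arg(column, c("latest", "5y", "10y", "ever"))
  tab[, c("criterion", column)]
}

#' Published WATCH grade-by-sputum-phenotype cell counts
#'
#' The 4x4 cross-tabulation of eosinophil gradient grade (highest-ever
#' BEC window) against induced-sputum granulocyte phenotype reported for
#' the 130-patient WATCH sputum subcohort.
#'
#' @return A tibble with columns `grade` (3 down to 0), `phenotype`, and
#'   integer `count`; the counts sum to 130.
#' @examples
#' sum(watch_table2_cells()$count) # 130
#' @export
watch_table2_cells <- function() {
  tidyr::expand_grid(
    grade = 3:0,
    phenotype = factor(sputum_phenotype_levels,
                       levels = sputum_phenotype_levels)
  ) |>
    dplyr::mutate(count = c(
      45L, 13L, 14L, 35L,  # grade 3
      2L,  3L,  5L,  3L,   # grade 2
      0L,  0L,  3L,  6L,   # grade 1
      0L,  0L,  0L,  1L    # grade 0
    ))
}

# Canonical witness features per criterion: a single BEC observation on
# the enrolment day plus the minimal flag pattern that makes exactly
# that decision-table row fire. Any interior point of each band works;
# fixed constants make round-trips exact. The anti-IL-5 witness carries
# a low in-band count so the BEC >= 300 row cannot pre-empt it.
criterion_witness <- function(criterion) {
  w <- list(
    BEC_GE_300    = list(bec = 350, ocs = FALSE, il5 = FALSE, np = FALSE, feno = 10),
    ANTI_IL5      = list(bec = 100, ocs = FALSE, il5 = TRUE,  np = FALSE, feno = 10),
    MID_OCS       = list(bec = 200, ocs = TRUE,  il5 = FALSE, np = FALSE, feno = 10),
    MID_T2_MULTI  = list(bec = 200, ocs = FALSE, il5 = FALSE, np = TRUE,  feno = 30),
    MID_T2_SINGLE = list(bec = 200, ocs = FALSE, il5 = FALSE, np = TRUE,  feno = 10),
    MID_T2_NONE   = list(bec = 200, ocs = FALSE, il5 = FALSE, np = FALSE, feno = 10),
    LOW_OCS       = list(bec = 100, ocs = TRUE,  il5 = FALSE, np = FALSE, feno = 10),
    LOW_T2_ANY    = list(bec = 100, ocs = FALSE, il5 = FALSE, np = TRUE,  feno = 10),
    LOW_T2_NONE   = list(bec = 100, ocs = FALSE, il5 = FALSE, np = FALSE, feno = 10)
  )
  w[[criterion]]
}

# Grade witnesses reuse criterion witnesses via a representative row.
grade_witness_criterion <- c(
  `3` = "BEC_GE_300", `2` = "MID_T2_SINGLE",
  `1` = "MID_T2_NONE", `0` = "LOW_T2_NONE"
)

# Canonical sputum differentials: an interior point of each phenotype
# region.
phenotype_witness <- list(
  eosinophilic   = c(eos = 5, neut = 40),
  mixed_granular = c(eos = 5, neut = 70),
  neutrophilic   = c(eos = 1, neut = 70),
  pauci_granular = c(eos = 1, neut = 40)
)

fixture_enrolment_date <- as.Date("2020-01-01")

witness_patient_rows <- function(ids, witness) {
  tibble::tibble(
    patient_id = ids,
    enrolment_date = fixture_enrolment_date,
    on_anti_il5 = witness$il5,
    maintenance_ocs = witness$ocs,
    nasal_polyps = witness$np,
    feno_ppb = witness$feno,
    age_at_diagnosis = 10,   # childhood onset: adult_onset stays FALSE
    age_at_enrolment = 50
  )
}

#' Rebuild a cohort from per-criterion counts
#'
#' Deterministically emits, for each decision-table criterion, the
#' requested number of patients whose single-observation BEC history and
#' feature flags are canonical witnesses of exactly that criterion, under
#' any observation window (the one observation sits on the enrolment
#' day). Running [grade_cohort()] on the result returns the input counts
#' exactly — the round-trip that turns a printed summary table back into
#' a gradable cohort.
#'
#' @param counts Named non-negative integer vector (names from
#'   [criterion_levels]), or a two-column data frame
#'   (`criterion`, count).
#' @param window A [window_spec()]; recorded for downstream use, the
#'   witnesses grade identically under every window. Default `"ever"`.
#' @return An [eos_cohort()] with `sum(counts)` patients.
#' @examples
#' cohort <- fixture_from_criterion_counts(watch_table1_counts("ever"))
#' nrow(cohort$patients) # 500
#' @export
fixture_from_criterion_counts <- function(counts,
                                          window = window_spec("ever")) {
  if (is.data.frame(counts)) {
    stopifnot(ncol(counts) == 2, "criterion" %in% names(counts))
    value_col <- setdiff(names(counts), "criterion")
    counts <- stats::setNames(counts[[value_col]],
                              as.character(counts$criterion))
  }
  if (length(counts) > 0 &&
      (is.null(names(counts)) || !all(names(counts) %in% criterion_levels))) {
    rlang::abort("`counts` must be named by decision-table criteria.",
                 class = "eosgradient_validation_error")
  }
  if (any(counts < 0)) {
    rlang::abort("`counts` must be non-negative.",
                 class = "eosgradient_validation_error")
  }
  stopifnot(inherits(window, "window_spec"))

  rows <- purrr::imap(counts[counts > 0], function(n, crit) {
    ids <- sprintf("%s_%03d", crit, seq_len(n))
    witness_patient_rows(ids, criterion_witness(crit)) |>
      dplyr::mutate(.bec = criterion_witness(crit)$bec)
  })
  if (length(rows) == 0) {
    patients <- witness_patient_rows(character(0),
                                     criterion_witness("LOW_T2_NONE"))
    bec <- tibble::tibble(patient_id = character(0),
                          obs_date = as.Date(character(0)),
                          count = integer(0))
    return(eos_cohort(patients, bec))
  }
  all_rows <- dplyr::bind_rows(rows)
  patients <- dplyr::select(all_rows, -".bec")
  bec <- tibble::tibble(
    patient_id = all_rows$patient_id,
    obs_date = all_rows$enrolment_date,
    count = as.integer(all_rows$.bec)
  )
  eos_cohort(patients, bec)
}

#' Rebuild a sputum subcohort from grade-by-phenotype cell counts
#'
#' Emits, per non-zero cell, that many patients combining a canonical
#' grade witness (single-observation BEC history and flags that produce
#' the cell's grade) with a canonical sputum differential interior to the
#' cell's phenotype region (eosinophilic: 5/40, mixed granular: 5/70,
#' neutrophilic: 1/70, pauci-granular: 1/40). [grade_cohort()] plus
#' [classify_sputum_cohort()] and [cross_tabulate()] reproduce the input
#' cells exactly.
#'
#' @param cells A data frame with columns `grade` (0-3), `phenotype`
#'   (values in [sputum_phenotype_levels]) and `count` (non-negative).
#' @return An [eos_cohort()] whose sputum table covers every patient.
#' @examples
#' sub <- fixture_from_crosstab(watch_table2_cells())
#' nrow(sub$sputum) # 130
#' @export
fixture_from_crosstab <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("grade", "phenotype", "count") %in% names(cells)))
  if (any(cells$count < 0)) {
    rlang::abort("`count` must be non-negative.",
                 class = "eosgradient_validation_error")
  }
  if (!all(cells$grade %in% 0:3) ||
      !all(as.character(cells$phenotype) %in% sputum_phenotype_levels)) {
    rlang::abort("`cells` must use grades 0-3 and the four phenotype labels.",
                 class = "eosgradient_validation_error")
  }
  cells <- cells[cells$count > 0, c("grade", "phenotype", "count"),
                 drop = FALSE]
  if (nrow(cells) == 0) {
    empty <- fixture_from_criterion_counts(integer(0))
    empty$sputum <- tibble::tibble(patient_id = character(0),
                                   eos_pct = numeric(0),
                                   neut_pct = numeric(0))
    return(empty)
  }
  parts <- purrr::pmap(cells, function(grade, phenotype, count) {
    crit <- grade_witness_criterion[[as.character(grade)]]
    w <- criterion_witness(crit)
    ids <- sprintf("G%d_%s_%03d", grade, as.character(phenotype),
                   seq_len(count))
    sp <- phenotype_witness[[as.character(phenotype)]]
    list(
      patients = witness_patient_rows(ids, w),
      bec = tibble::tibble(patient_id = ids,
                           obs_date = fixture_enrolment_date,
                           count = as.integer(w$bec)),
      sputum = tibble::tibble(patient_id = ids,
                              eos_pct = sp[["eos"]],
                              neut_pct = sp[["neut"]])
    )
  })
  eos_cohort(
    patients = dplyr::bind_rows(purrr::map(parts, "patients")),
    bec = dplyr::bind_rows(purrr::map(parts, "bec")),
    sputum = dplyr::bind_rows(purrr::map(parts, "sputum"))
  )
}
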