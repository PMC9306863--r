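#' Decision-table criteria and their grades
#'
#' The nine mutually exclusive rows of the eosinophil gradient decision
#' table, in the order they are conventionally printed, and the ordinal
#' grade each one assigns. `BEC_GE_300` outranks `ANTI_IL5` so that every
#' gradable patient matches exactly one row (both assign grade 3, but the
#' per-criterion counts must partition the cohort).
#'
#' @format `criterion_levels` is a character vector of length 9;
#'   `criterion_grade` is a named integer vector mapping criterion to
#'   grade.
#' @export
criterion_levels <- c(
  "BEC_GE_300", "ANTI_IL5", "MID_OCS", "MID_T2_MULTI",
  "MID_T2_SINGLE", "MID_T2_NONE", "LOW_OCS", "LOW_T2_ANY", "LOW_T2_NONE"
)

#' @rdname criterion_levels
#' @export
criterion_grade <- c(
  BEC_GE_300 = 3L, ANTI_IL5 = 3L, MID_OCS = 3L, MID_T2_MULTI = 3L,
  MID_T2_SINGLE = 2L, MID_T2_NONE = 1L,
  LOW_OCS = 2L, LOW_T2_ANY = 1L, LOW_T2_NONE = 0L
)

# Vectorised decision table. bec may contain NA (ungradable unless on
# anti-IL-5). Returns tibble(grade, criterion); ungradable rows have NA
# in both.
decide_criterion <- function(bec, flags, thresholds) {
  t2 <- flags$nasal_polyps + flags$feno_elevated + flags$adult_onset
  t2cut <- thresholds$t2_feature_count_for_grade3
  criterion <- dplyr::case_when(
    !is.na(bec) & bec >= thresholds$bec_high ~ "BEC_GE_300",
    flags$on_anti_il5 ~ "ANTI_IL5",
    is.na(bec) ~ NA_character_,
    bec >= thresholds$bec_low & flags$maintenance_ocs ~ "MID_OCS",
    bec >= thresholds$bec_low & t2 >= t2cut ~ "MID_T2_MULTI",
    bec >= thresholds$bec_low & t2 >= 1 ~ "MID_T2_SINGLE",
    bec >= thresholds$bec_low ~ "MID_T2_NONE",
    flags$maintenance_ocs ~ "LOW_OCS",
    t2 >= 1 ~ "LOW_T2_ANY",
    .default = "LOW_T2_NONE"
  )
  tibble::tibble(
    grade = unname(criterion_grade[criterion]),
    criterion = factor(criterion, levels = criterion_levels)
  )
}

#' Assign an eosinophil gradient grade to one patient
#'
#' Applies the decision table to a selected blood eosinophil count and a
#' set of feature flags. Evaluation order: (1) BEC at or above `bec_high`
#' assigns grade 3 (`BEC_GE_300`); (2) otherwise anti-IL-5 therapy
#' assigns grade 3 (`ANTI_IL5`) even when the BEC is missing; (3) a
#' missing BEC is otherwise ungradable; (4) middle band
#' `[bec_low, bec_high)`: maintenance OCS gives grade 3 (`MID_OCS`), else
#' the count of type-2 features (nasal polyps, elevated FeNO, adult
#' onset) decides — at least `t2_feature_count_for_grade3` gives grade 3
#' (`MID_T2_MULTI`), at least one gives grade 2 (`MID_T2_SINGLE`), none
#' gives grade 1 (`MID_T2_NONE`); (5) low band below `bec_low`:
#' maintenance OCS gives grade 2 (`LOW_OCS`), any type-2 feature grade 1
#' (`LOW_T2_ANY`), none grade 0 (`LOW_T2_NONE`).
#'
#' @param bec Selected blood eosinophil count in cells/uL, or `NA`.
#' @param flags A one-row tibble or named list with logicals
#'   `nasal_polyps`, `feno_elevated`, `adult_onset`, `maintenance_ocs`,
#'   `on_anti_il5` (as from [derive_flags()]).
#' @param thresholds A [grading_thresholds()] object.
#' @return A list of class `grade_assignment` with elements `grade`
#'   (integer 0-3, `NA` if ungradable), `criterion` (factor over the nine
#'   decision-table rows, `NA` if ungradable), `bec_used` and
#'   `ungradable` (logical).
#' @examples
#' th <- grading_thresholds()
#' fl <- list(nasal_polyps = FALSE, feno_elevated = FALSE,
#'            adult_onset = FALSE, maintenance_ocs = FALSE,
#'            on_anti_il5 = FALSE)
#' assign_grade(350, fl, th)$grade       # 3 via BEC_GE_300
#' assign_grade(100, fl, th)$grade       # 0 via LOW_T2_NONE
#' fl$maintenance_ocs <- TRUE
#' assign_grade(200, fl, th)$criterion   # MID_OCS
#' @export
assign_grade <- function(bec, flags, thresholds = grading_thresholds()) {
  stopifnot(inherits(thresholds, "grading_thresholds"))
  if (!is.null(bec) && length(bec) == 1L && !is.na(bec) && bec < 0) {
    rlang::abort("`bec` must be non-negative.",
                 class = "eosgradient_validation_error")
  }
  stopifnot(length(bec) == 1L)
  flags <- tibble::as_tibble(flags[c("nasal_polyps", "feno_elevated",
                                     "adult_onset", "maintenance_ocs",
                                     "on_anti_il5")])
  stopifnot(nrow(flags) == 1L, all(vapply(flags, is.logical, logical(1))))
  d <- decide_criterion(as.numeric(bec), flags, thresholds)
  structure(
    list(grade = d$grade, criterion = d$criterion,
         bec_used = as.numeric(bec), ungradable = is.na(d$criterion)),
    class = "grade_assignment"
  )
}

#' @export
print.grade_assignment <- function(x, ...) {
  if (x$ungradable) {
    cat("<grade_assignment> ungradable (no eligible BEC, not on anti-IL-5)\n")
  } else {
    cat(sprintf("<grade_assignment> grade %d via %s (BEC %s cells/uL)\n",
                x$grade, as.character(x$criterion),
                if (is.na(x$bec_used)) "n/a" else format(x$bec_used)))
  }
  invisible(x)
}

#' Grade a whole cohort under one observation window
#'
#' Runs the full per-patient pipeline — windowed BEC selection
#' ([select_bec()]), feature-flag derivation ([derive_flags()]) and the
#' decision table ([assign_grade()]) — over a cohort, and tallies the
#' per-criterion counts.
#'
#' @param cohort An [eos_cohort()].
#' @param window A [window_spec()].
#' @param thresholds A [grading_thresholds()] object.
#' @param quiet Passed to [derive_flags()]; default `TRUE`.
#' @return A list of class `cohort_grading` with elements:
#'   * `assignments`: tibble with one row per patient (`patient_id`,
#'     `bec_used`, `source_date`, `n_observations_in_window`, `grade`,
#'     `criterion`, `ungradable`);
#'   * `criterion_counts`: a `criterion_count_table` (see
#'     [criterion_count_table()]);
#'   * `window`: the window used.
#' @examples
#' cohort <- fixture_from_criterion_counts(c(BEC_GE_300 = 2, LOW_T2_NONE = 1))
#' g <- grade_cohort(cohort, window_spec("ever"))
#' g$assignments$grade  # 3 3 0
#' @export
grade_cohort <- function(cohort, window, thresholds = grading_thresholds(),
                         quiet = TRUE) {
  stopifnot(inherits(cohort, "eos_cohort"), inherits(window, "window_spec"),
            inherits(thresholds, "grading_thresholds"))
  patients <- cohort$patients
  sel <- select_bec_cohort(cohort$bec, patients, window)
  flags <- derive_flags(patients, thresholds, quiet = quiet)
  d <- decide_criterion(sel$value, flags, thresholds)
  assignments <- tibble::tibble(
    patient_id = patients$patient_id,
    bec_used = sel$value,
    source_date = sel$source_date,
    n_observations_in_window = sel$n_observations_in_window,
    grade = d$grade,
    criterion = d$criterion,
    ungradable = is.na(d$criterion)
  )
  counts_vec <- table(factor(assignments$criterion, levels = criterion_levels))
  cct <- criterion_count_table(
    counts = stats::setNames(as.integer(counts_vec), criterion_levels),
    window = window,
    ungradable = sum(assignments$ungradable)
  )
  structure(list(assignments = assignments, criterion_counts = cct,
                 window = window),
            class = "cohort_grading")
}

#' @export
print.cohort_grading <- function(x, ...) {
  cat(sprintf("<cohort_grading> window = %s\n", format_window(x$window)))
  print(grade_distribution(x$criterion_counts))
  invisible(x)
}

#' Per-criterion cohort counts
#'
#' Holds the number of patients matching each decision-table row under
#' one window, plus the ungradable count — the machine-readable form of
#' one column of a published grading table.
#'
#' @param counts Named non-negative integer vector over (a subset of) the
#'   nine criteria in [criterion_levels].
#' @param window A [window_spec()].
#' @param ungradable Number of patients with no eligible BEC and no
#'   anti-IL-5 therapy.
#' @return An object of class `criterion_count_table`: a tibble with
#'   columns `criterion`, `grade`, `count`, and attributes `window` and
#'   `ungradable`.
#' @export
criterion_count_table <- function(counts, window, ungradable = 0L) {
  stopifnot(inherits(window, "window_spec"))
  if (is.null(names(counts)) || !all(names(counts) %in% criterion_levels)) {
    rlang::abort("`counts` must be named by decision-table criteria.",
                 class = "eosgradient_validation_error")
  }
  if (any(counts < 0) || any(ungradable < 0)) {
    rlang::abort("Counts must be non-negative.",
                 class = "eosgradient_validation_error")
  }
  full <- stats::setNames(integer(length(criterion_levels)), criterion_levels)
  full[names(counts)] <- as.integer(counts)
  out <- tibble::tibble(
    criterion = factor(criterion_levels, levels = criterion_levels),
    grade = unname(criterion_grade[criterion_levels]),
    count = unname(full)
  )
  attr(out, "window") <- window
  attr(out, "ungradable") <- as.integer(ungradable)
  class(out) <- c("criterion_count_table", class(out))
  out
}
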