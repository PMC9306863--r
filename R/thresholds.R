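#' Grading thresholds for the eosinophil gradient algorithm
#'
#' Bundles the numeric cut-points used by the decision table. Defaults are
#' the published values: blood eosinophil count (BEC) bands at 150 and
#' 300 cells/uL, FeNO elevation strictly above 25 ppb, adult onset at a
#' diagnosis age of 18 years or later, and two or more type-2 features
#' required for the middle-band grade-3 row.
#'
#' @param bec_high Upper BEC band boundary, cells/uL. Counts at or above
#'   this value are graded 3 outright.
#' @param bec_low Lower BEC band boundary, cells/uL. The middle band is
#'   `[bec_low, bec_high)`; counts below `bec_low` form the low band.
#' @param feno_cut FeNO threshold in ppb; elevation is strict (`> feno_cut`).
#' @param adult_onset_age Diagnosis age in years at or above which asthma
#'   counts as adult-onset.
#' @param t2_feature_count_for_grade3 Number of type-2 features (nasal
#'   polyps, elevated FeNO, adult onset) needed for the middle-band
#'   grade-3 row. The published table's wording admits either 2 or 3;
#'   the default 2 reflects the "at least two" reading of the source
#'   registry description.
#'
#' @return An object of class `grading_thresholds`.
#' @examples
#' grading_thresholds()
#' grading_thresholds(t2_feature_count_for_grade3 = 3) # literal ">2" reading
#' @export
grading_thresholds <- function(bec_high = 300,
                               bec_low = 150,
                               feno_cut = 25,
                               adult_onset_age = 18,
                               t2_feature_count_for_grade3 = 2) {
  stopifnot(
    is.numeric(bec_high), length(bec_high) == 1L,
    is.numeric(bec_low), length(bec_low) == 1L,
    is.numeric(feno_cut), length(feno_cut) == 1L,
    is.numeric(adult_onset_age), length(adult_onset_age) == 1L,
    is.numeric(t2_feature_count_for_grade3),
    length(t2_feature_count_for_grade3) == 1L
  )
  if (!(bec_low > 0 && bec_low < bec_high)) {
    rlang::abort("`bec_low` must satisfy 0 < bec_low < bec_high.",
                 class = "eosgradient_validation_error")
  }
  if (feno_cut <= 0) {
    rlang::abort("`feno_cut` must be positive.",
                 class = "eosgradient_validation_error")
  }
  if (!t2_feature_count_for_grade3 %in% 1:3) {
    rlang::abort("`t2_feature_count_for_grade3` must be 1, 2 or 3.",
                 class = "eosgradient_validation_error")
  }
  structure(
    list(
      bec_high = bec_high,
      bec_low = bec_low,
      feno_cut = feno_cut,
      adult_onset_age = adult_onset_age,
      t2_feature_count_for_grade3 = as.integer(t2_feature_count_for_grade3)
    ),
    class = "grading_thresholds"
  )
}

#' @export
print.grading_thresholds <- function(x, ...) {
  cat("Eosinophil gradient thresholds\n")
  cat(sprintf("  BEC bands: <%g / [%g, %g) / >=%g cells/uL\n",
              x$bec_low, x$bec_low, x$bec_high, x$bec_high))
  cat(sprintf("  FeNO elevated: > %g ppb\n", x$feno_cut))
  cat(sprintf("  Adult onset: diagnosis age >= %g years\n", x$adult_onset_age))
  cat(sprintf("  T2 features for middle-band grade 3: >= %d of 3\n",
              x$t2_feature_count_for_grade3))
  invisible(x)
}

#' Blood eosinophil observation window
#'
#' Specifies which historical blood eosinophil observations a grading run
#' may use, relative to the enrolment date. Three modes mirror the
#' published column heads: `"latest"` (most recent pre-enrolment result
#' only), `"lookback"` (highest result within the last `years` years,
#' closed interval, one year = 365.25 days), and `"ever"` (highest
#' pre-enrolment result on record). Observations after enrolment are never
#' eligible in any mode.
#'
#' @param mode One of `"latest"`, `"lookback"`, `"ever"`.
#' @param years Lookback length in years; required (and only allowed) for
#'   `mode = "lookback"`; must be positive.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec("latest")
#' window_spec("lookback", years = 5)
#' @seealso [parse_window()] for the compact string form used by the
#'   command-line interface.
#' @export
window_spec <- function(mode = c("latest", "lookback", "ever"), years = NULL) {
  mode <- match.arg(mode)
  if (mode == "lookback") {
    if (is.null(years) || !is.numeric(years) || length(years) != 1L ||
        is.na(years) || years <= 0) {
      rlang::abort("`years` must be a single positive number for lookback windows.",
                   class = "eosgradient_validation_error")
    }
  } else if (!is.null(years)) {
    rlang::abort(sprintf("`years` is only meaningful for mode = \"lookback\" (got mode = \"%s\").", mode),
                 class = "eosgradient_validation_error")
  }
  structure(list(mode = mode, years = years), class = "window_spec")
}

#' Parse a compact window string
#'
#' Accepts `"latest"`, `"ever"`, shorthand like `"5y"` or `"10y"`, and the
#' explicit `"lookback:<years>"` form.
#'
#' @param x A single string.
#' @return A [window_spec()].
#' @examples
#' parse_window("5y")
#' parse_window("lookback:7.5")
#' @export
parse_window <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% c("latest", "ever")) return(window_spec(x))
  if (grepl("^[0-9]+(\\.[0-9]+)?y$", x)) {
    return(window_spec("lookback", years = as.numeric(sub("y$", "", x))))
  }
  if (grepl("^lookback:[0-9]+(\\.[0-9]+)?$", x)) {
    return(window_spec("lookback", years = as.numeric(sub("^lookback:", "", x))))
  }
  rlang::abort(sprintf("Cannot parse window \"%s\"; expected latest, ever, <k>y or lookback:<years>.", x),
               class = "eosgradient_validation_error")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(format_window(x), "\n", sep = "")
  invisible(x)
}

#' Format a window spec as a short label
#' @param window A [window_spec()].
#' @return A single string such as `"latest"` or `"lookback_5y"`.
#' @export
format_window <- function(window) {
  stopifnot(inherits(window, "window_spec"))
  if (window$mode == "lookback") {
    sprintf("lookback_%gy", window$years)
  } else {
    window$mode
  }
}
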