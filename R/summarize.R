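#' Per-grade counts and percentages from a criterion count table
#'
#' Sums the per-criterion counts into grade totals and expresses each as
#' a percentage of the gradable total (the sum of all criterion counts),
#' rounded to one decimal place — the reporting convention of the
#' published grading tables. Ungradable patients are excluded from the
#' denominator and reported separately via the table's attribute.
#'
#' @param table A [criterion_count_table()].
#' @return A tibble with columns `grade` (3 down to 0), `count`, `pct`.
#' @examples
#' cct <- criterion_count_table(
#'   c(BEC_GE_300 = 163, ANTI_IL5 = 39, MID_OCS = 15, MID_T2_MULTI = 8,
#'     MID_T2_SINGLE = 28, MID_T2_NONE = 28, LOW_OCS = 71,
#'     LOW_T2_ANY = 82, LOW_T2_NONE = 66),
#'   window_spec("latest")
#' )
#' grade_distribution(cct) # grade 3: 225 (45.0%)
#' @export
grade_distribution <- function(table) {
  stopifnot(inherits(table, "criterion_count_table"))
  total <- sum(table$count)
  out <- table |>
    dplyr::group_by(grade = .data$grade) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$grade))
  out$pct <- if (total > 0) round(100 * out$count / total, 1) else NA_real_
  out
}

#' Cross-tabulate eosinophil grades against sputum phenotypes
#'
#' Builds the 4x4 grade-by-phenotype contingency table for patients who
#' have both a grade and a classified sputum differential (inner join on
#' `patient_id`; ungradable patients are dropped).
#'
#' @param assignments A grade-assignment tibble (as in the `assignments`
#'   element of [grade_cohort()]'s result) with `patient_id` and `grade`.
#' @param phenotypes A tibble with `patient_id` and a factor `phenotype`
#'   (as from [classify_sputum_cohort()]).
#' @return An object of class `sputum_crosstab`: an integer matrix with
#'   rows grade 3..0 and columns the four phenotypes, with attributes
#'   `row_pct` (row percentages to 1 decimal place) and `n` (number of
#'   paired patients).
#' @export
cross_tabulate <- function(assignments, phenotypes) {
  paired <- dplyr::inner_join(
    dplyr::select(assignments, "patient_id", "grade"),
    dplyr::select(phenotypes, "patient_id", "phenotype"),
    by = "patient_id"
  )
  paired <- paired[!is.na(paired$grade), , drop = FALSE]
  cells <- table(
    grade = factor(paired$grade, levels = 3:0),
    phenotype = factor(paired$phenotype, levels = sputum_phenotype_levels)
  )
  m <- matrix(as.integer(cells), nrow = 4, ncol = 4,
              dimnames = dimnames(cells))
  row_tot <- rowSums(m)
  row_pct <- sweep(m, 1, pmax(row_tot, 1), "/") * 100
  row_pct <- round(row_pct, 1)
  row_pct[row_tot == 0, ] <- NA_real_
  structure(m, class = c("sputum_crosstab", "matrix", "array"),
            row_pct = row_pct, n = nrow(paired))
}

#' @export
print.sputum_crosstab <- function(x, ...) {
  cat(sprintf("<sputum_crosstab> %d paired patients\n", attr(x, "n")))
  print(unclass_crosstab(x))
  invisible(x)
}

unclass_crosstab <- function(x) {
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  m
}

#' Discordance between blood-based grade and sputum phenotype
#'
#' Computes the two derived proportions used to quantify how often the
#' blood-based gradient and a single sputum snapshot disagree:
#' (a) the percentage of grade-3 patients whose sputum shows no
#' eosinophilia (phenotype neutrophilic or pauci-granular), and (b) the
#' percentage of sputum-eosinophilic patients (eosinophilic or mixed
#' granular, i.e. eosinophils at or above the cut) who also meet the
#' neutrophilia cut (mixed granular). Both are rounded to the nearest
#' whole percent, matching how such figures are conventionally reported.
#'
#' @param tab A [cross_tabulate()] result.
#' @return A list with elements `grade3_without_sputum_eosinophilia_pct`
#'   and `neutrophilic_among_sputum_eosinophilic_pct` (either may be
#'   `NA` when its denominator is empty).
#' @export
discordance_stats <- function(tab) {
  stopifnot(inherits(tab, "sputum_crosstab"))
  m <- unclass_crosstab(tab)
  if (sum(m) == 0) {
    rlang::abort("Cross-tabulation is empty.",
                 class = "eosgradient_validation_error")
  }
  g3 <- m["3", ]
  g3_total <- sum(g3)
  a <- if (g3_total > 0) {
    round(100 * (g3[["neutrophilic"]] + g3[["pauci_granular"]]) / g3_total)
  } else NA_real_
  eos_like <- sum(m[, "eosinophilic"]) + sum(m[, "mixed_granular"])
  b <- if (eos_like > 0) {
    round(100 * sum(m[, "mixed_granular"]) / eos_like)
  } else NA_real_
  list(
    grade3_without_sputum_eosinophilia_pct = a,
    neutrophilic_among_sputum_eosinophilic_pct = b
  )
}

#' Compare grade >= 2 patients against grade 0 patients
#'
#' Splits a graded cohort into the "at least likely eosinophilic"
#' (grade 2 or higher) and "unlikely" (grade 0) groups — grade-1 and
#' ungradable patients are excluded — and compares configured variables
#' between them. Continuous variables get group medians and a two-sided
#' Wilcoxon rank-sum p-value; binary variables get group proportions and
#' a chi-squared p-value, switching to Fisher's exact test when any
#' expected cell count is below 5. No multiplicity correction is
#' applied.
#'
#' @param patients A validated patient table containing the variables.
#' @param assignments A grade-assignment tibble with `patient_id`,
#'   `grade`.
#' @param continuous Character vector of numeric column names in
#'   `patients` to compare.
#' @param binary Character vector of logical column names to compare.
#' @return A tibble with one row per variable: `variable`, `type`,
#'   `summary_high` / `summary_low` (median or proportion in the
#'   grade >= 2 and grade-0 groups), `test`, `p_value`, `computable`.
#'   When either group is empty every row has `computable = FALSE` and
#'   `NA` statistics rather than an error.
#' @export
compare_groups <- function(patients, assignments,
                           continuous = c("age_at_enrolment", "feno_ppb",
                                          "age_at_diagnosis"),
                           binary = c("nasal_polyps")) {
  patients <- validate_patients(patients)
  df <- dplyr::inner_join(
    patients, dplyr::select(assignments, "patient_id", "grade"),
    by = "patient_id"
  )
  df <- df[!is.na(df$grade) & df$grade != 1L, , drop = FALSE]
  df$group <- ifelse(df$grade >= 2L, "high", "low")
  n_high <- sum(df$group == "high")
  n_low <- sum(df$group == "low")

  one_var <- function(v, type) {
    base <- tibble::tibble(
      variable = v, type = type,
      summary_high = NA_real_, summary_low = NA_real_,
      test = NA_character_, p_value = NA_real_, computable = FALSE
    )
    if (n_high == 0 || n_low == 0) return(base)
    x <- df[[v]][df$group == "high"]
    y <- df[[v]][df$group == "low"]
    if (type == "continuous") {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) return(base)
      p <- tryCatch(
        stats::wilcox.test(x, y, exact = FALSE)$p.value,
        error = function(e) NA_real_
      )
      base$summary_high <- stats::median(x)
      base$summary_low <- stats::median(y)
      base$test <- "wilcoxon_rank_sum"
      base$p_value <- p
      base$computable <- !is.na(p)
    } else {
      tab <- table(factor(df$group, levels = c("high", "low")),
                   factor(df[[v]], levels = c(FALSE, TRUE)))
      expected <- tryCatch(
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected),
        error = function(e) NULL
      )
      if (is.null(expected)) return(base)
      if (any(expected < 5)) {
        p <- tryCatch(stats::fisher.test(tab)$p.value,
                      error = function(e) NA_real_)
        base$test <- "fisher_exact"
      } else {
        p <- tryCatch(stats::chisq.test(tab, correct = FALSE)$p.value,
                      error = function(e) NA_real_)
        base$test <- "chi_squared"
      }
      base$summary_high <- mean(df[[v]][df$group == "high"])
      base$summary_low <- mean(df[[v]][df$group == "low"])
      base$p_value <- p
      base$computable <- !is.na(p)
    }
    base
  }

  dplyr::bind_rows(
    purrr::map(continuous, one_var, type = "continuous"),
    purrr::map(binary, one_var, type = "binary")
  )
}
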