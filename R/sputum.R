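#' Sputum granulocyte phenotype labels
#'
#' The four labels of the induced-sputum granulocyte partition, at the
#' conventional 2% eosinophil and 61% neutrophil cuts.
#' @export
sputum_phenotype_levels <- c(
  "eosinophilic", "mixed_granular", "neutrophilic", "pauci_granular"
)

#' Classify induced-sputum differentials into granulocyte phenotypes
#'
#' Partitions the (eosinophil %, neutrophil %) plane at 2% eosinophils
#' and 61% neutrophils, both inclusive on the high side:
#' eosinophilic (eos >= 2, neut < 61), mixed granular (eos >= 2,
#' neut >= 61), neutrophilic (eos < 2, neut >= 61), pauci-granular
#' (eos < 2, neut < 61). Percentages are of non-squamous cells; slide
#' counting and squamous exclusion happen upstream.
#'
#' @param eos_pct,neut_pct Numeric vectors of eosinophil and neutrophil
#'   percentages, each in \[0, 100\] with `eos_pct + neut_pct <= 100`.
#' @param eos_cut,neut_cut The partition cuts; defaults 2 and 61.
#' @return A factor over [sputum_phenotype_levels], same length as the
#'   inputs.
#' @examples
#' classify_sputum(c(2, 1.9, 0, 5), c(60.9, 61, 0, 70))
#' @export
classify_sputum <- function(eos_pct, neut_pct, eos_cut = 2, neut_cut = 61) {
  stopifnot(is.numeric(eos_pct), is.numeric(neut_pct),
            length(eos_pct) == length(neut_pct))
  if (anyNA(eos_pct) || anyNA(neut_pct) ||
      any(eos_pct < 0 | eos_pct > 100 | neut_pct < 0 | neut_pct > 100)) {
    rlang::abort("Sputum percentages must be complete and within [0, 100].",
                 class = "eosgradient_validation_error")
  }
  if (any(eos_pct + neut_pct > 100)) {
    rlang::abort("eos_pct + neut_pct must not exceed 100.",
                 class = "eosgradient_validation_error")
  }
  label <- dplyr::case_when(
    eos_pct >= eos_cut & neut_pct < neut_cut ~ "eosinophilic",
    eos_pct >= eos_cut ~ "mixed_granular",
    neut_pct >= neut_cut ~ "neutrophilic",
    .default = "pauci_granular"
  )
  factor(label, levels = sputum_phenotype_levels)
}

#' Classify a cohort's sputum subtable
#'
#' Convenience wrapper: classifies every differential in a cohort's
#' sputum table and returns it with a `phenotype` column appended.
#'
#' @param cohort An [eos_cohort()] with a non-`NULL` sputum table.
#' @return The sputum tibble with an added factor column `phenotype`.
#' @export
classify_sputum_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "eos_cohort"))
  if (is.null(cohort$sputum)) {
    rlang::abort("Cohort has no sputum table.",
                 class = "eosgradient_validation_error")
  }
  sputum <- cohort$sputum
  sputum$phenotype <- classify_sputum(sputum$eos_pct, sputum$neut_pct)
  sputum
}
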