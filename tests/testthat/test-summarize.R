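latest_counts <- c(BEC_GE_300 = 163, ANTI_IL5 = 39, MID_OCS = 15,
                   MID_T2_MULTI = 8, MID_T2_SINGLE = 28, MID_T2_NONE = 28,
                   LOW_OCS = 71, LOW_T2_ANY = 82, LOW_T2_NONE = 66)

test_that("grade_distribution sums criteria into grades with 1-dp percentages", {
  cct <- criterion_count_table(latest_counts, window_spec("latest"))
  d <- grade_distribution(cct)
  expect_equal(d$grade, c(3, 2, 1, 0))
  expect_equal(d$count, c(225, 99, 110, 66))
  expect_equal(d$pct, c(45.0, 19.8, 22.0, 13.2))
  expect_lt(abs(sum(d$pct) - 100), 0.1)

  ever <- criterion_count_table(
    c(BEC_GE_300 = 359, ANTI_IL5 = 8, MID_OCS = 17, MID_T2_MULTI = 3,
      MID_T2_SINGLE = 25, MID_T2_NONE = 25, LOW_OCS = 20, LOW_T2_ANY = 22,
      LOW_T2_NONE = 21),
    window_spec("ever")
  )
  expect_equal(grade_distribution(ever)$pct[1], 77.4)

  single <- criterion_count_table(c(MID_OCS = 1), window_spec("latest"))
  ds <- grade_distribution(single)
  expect_equal(ds$pct[ds$grade == 3], 100.0)
})

test_that("cross_tabulate builds the 4x4 table over paired patients only", {
  assignments <- tibble::tibble(
    patient_id = c("a", "b", "c", "unpaired"),
    grade = c(3L, 3L, 0L, 2L)
  )
  phen <- tibble::tibble(
    patient_id = c("a", "b", "c", "nograde"),
    phenotype = factor(c("eosinophilic", "neutrophilic", "pauci_granular",
                         "mixed_granular"),
                       levels = sputum_phenotype_levels)
  )
  ct <- cross_tabulate(assignments, phen)
  expect_equal(attr(ct, "n"), 3L)
  expect_equal(sum(ct), 3L)
  expect_equal(ct["3", "eosinophilic"], 1L)
  expect_equal(ct["0", "pauci_granular"], 1L)
  rp <- attr(ct, "row_pct")
  expect_equal(rp["3", "eosinophilic"], 50.0)
  expect_equal(rp["0", "pauci_granular"], 100.0)
  expect_true(all(is.na(rp["1", ])))  # empty row has no percentages

  empty <- cross_tabulate(assignments[0, ], phen[0, ])
  expect_equal(sum(empty), 0L)
  expect_error(discordance_stats(empty),
               class = "eosgradient_validation_error")
})

test_that("discordance stats match a brute-force pass over patient records", {
  sub <- fixture_from_crosstab(watch_table2_cells())
  g <- grade_cohort(sub, window_spec("ever"))
  ph <- classify_sputum_cohort(sub)
  ct <- cross_tabulate(g$assignments, ph)
  ds <- discordance_stats(ct)

  # brute force over individual patients
  paired <- dplyr::inner_join(g$assignments, ph, by = "patient_id")
  g3 <- paired[paired$grade == 3, ]
  a <- round(100 * mean(g3$phenotype %in% c("neutrophilic", "pauci_granular")))
  eo <- paired[paired$phenotype %in% c("eosinophilic", "mixed_granular"), ]
  b <- round(100 * mean(eo$phenotype == "mixed_granular"))
  expect_equal(ds$grade3_without_sputum_eosinophilia_pct, a)
  expect_equal(ds$neutrophilic_among_sputum_eosinophilic_pct, b)

  # degenerate case: everyone grade 3 and purely eosinophilic
  all_eos <- fixture_from_crosstab(
    tibble::tibble(grade = 3, phenotype = "eosinophilic", count = 10)
  )
  g2 <- grade_cohort(all_eos, window_spec("ever"))
  ct2 <- cross_tabulate(g2$assignments, classify_sputum_cohort(all_eos))
  ds2 <- discordance_stats(ct2)
  expect_equal(ds2$grade3_without_sputum_eosinophilia_pct, 0)
  expect_equal(ds2$neutrophilic_among_sputum_eosinophilic_pct, 0)
})

make_groups <- function(n_high, n_low, age_high, age_low, sd = 0,
                        ages_high = NULL, ages_low = NULL) {
  high <- tibble::tibble(
    patient_id = sprintf("H%03d", seq_len(n_high)),
    enrolment_date = as.Date("2020-01-01"),
    on_anti_il5 = FALSE, maintenance_ocs = FALSE, nasal_polyps = TRUE,
    feno_ppb = 20, age_at_diagnosis = 10,
    age_at_enrolment = ages_high %||%
      pmax(20, age_high + stats::rnorm(n_high, sd = sd))
  )
  low <- tibble::tibble(
    patient_id = sprintf("L%03d", seq_len(n_low)),
    enrolment_date = as.Date("2020-01-01"),
    on_anti_il5 = FALSE, maintenance_ocs = FALSE, nasal_polyps = FALSE,
    feno_ppb = 20, age_at_diagnosis = 10,
    age_at_enrolment = ages_low %||%
      pmax(20, age_low + stats::rnorm(n_low, sd = sd))
  )
  patients <- dplyr::bind_rows(high, low)
  assignments <- tibble::tibble(
    patient_id = patients$patient_id,
    grade = c(rep(3L, n_high), rep(0L, n_low))
  )
  list(patients = patients, assignments = assignments)
}

test_that("compare_groups: identical groups give null results, empty groups flag not-computable", {
  set.seed(7)
  ages <- stats::rnorm(30, 50, 10)  # the same draw in both groups
  g <- make_groups(30, 30, 50, 50, ages_high = ages, ages_low = ages)
  res <- compare_groups(g$patients, g$assignments,
                        continuous = "age_at_enrolment",
                        binary = character(0))
  expect_true(res$computable)
  expect_equal(res$summary_high, res$summary_low)
  expect_gte(res$p_value, 0.99)

  g10 <- make_groups(1, 0, 50, 50)
  res10 <- compare_groups(g10$patients, g10$assignments)
  expect_true(all(!res10$computable))
  expect_true(all(is.na(res10$p_value)))
})

test_that("compare_groups detects a large age shift in most replicates", {
  set.seed(515)
  n_rep <- 200
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    g <- make_groups(25, 20, 55, 40, sd = 12)
    res <- compare_groups(g$patients, g$assignments,
                          continuous = "age_at_enrolment",
                          binary = character(0))
    p[r] <- res$p_value
  }
  expect_gt(mean(p < 0.05), 0.8)  # power check at a 15-year median shift
})

test_that("compare_groups runs binary comparisons with the exact-test fallback", {
  set.seed(11)
  g <- make_groups(40, 40, 55, 40, sd = 10)
  res <- compare_groups(g$patients, g$assignments,
                        continuous = character(0),
                        binary = "nasal_polyps")
  expect_true(res$computable)
  expect_equal(res$summary_high, 1)  # all high-group witnesses carry polyps
  expect_equal(res$summary_low, 0)
  expect_lt(res$p_value, 0.001)
  # tiny groups force expected cells < 5 and the exact test
  g2 <- make_groups(4, 4, 55, 40, sd = 10)
  res2 <- compare_groups(g2$patients, g2$assignments,
                         continuous = character(0), binary = "nasal_polyps")
  expect_equal(res2$test, "fisher_exact")
})
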