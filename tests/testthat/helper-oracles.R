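# Independent brute-force oracles and small construction helpers.
# The oracles are deliberately coded in a different style from the
# package internals (explicit row scan / filter-then-scan loops) so that
# agreement is a genuine cross-check, not a tautology.

# All-false flag set, with overrides.
flags0 <- function(...) {
  f <- list(nasal_polyps = FALSE, feno_elevated = FALSE,
            adult_onset = FALSE, maintenance_ocs = FALSE,
            on_anti_il5 = FALSE)
  utils::modifyList(f, list(...))
}

# Brute-force re-coding of the decision table as an ordered list of row
# predicates, scanned top to bottom. Returns list(grade, criterion) or
# NULL when ungradable.
oracle_grade <- function(bec, np, feno_el, adult, ocs, il5,
                         lo = 150, hi = 300, t2cut = 2) {
  t2 <- sum(np, feno_el, adult)
  rows <- list(
    list(ok = !is.na(bec) && bec >= hi,                      g = 3L, cr = "BEC_GE_300"),
    list(ok = il5,                                           g = 3L, cr = "ANTI_IL5"),
    list(ok = is.na(bec),                                    g = NA, cr = NA),
    list(ok = bec >= lo && ocs,                              g = 3L, cr = "MID_OCS"),
    list(ok = bec >= lo && !ocs && t2 >= t2cut,              g = 3L, cr = "MID_T2_MULTI"),
    list(ok = bec >= lo && !ocs && t2 >= 1 && t2 < t2cut,    g = 2L, cr = "MID_T2_SINGLE"),
    list(ok = bec >= lo && !ocs && t2 == 0,                  g = 1L, cr = "MID_T2_NONE"),
    list(ok = bec < lo && ocs,                               g = 2L, cr = "LOW_OCS"),
    list(ok = bec < lo && !ocs && t2 >= 1,                   g = 1L, cr = "LOW_T2_ANY"),
    list(ok = bec < lo && !ocs && t2 == 0,                   g = 0L, cr = "LOW_T2_NONE")
  )
  for (r in rows) {
    if (isTRUE(r$ok)) {
      if (is.na(r$cr)) return(NULL)
      return(list(grade = r$g, criterion = r$cr))
    }
  }
  stop("oracle fell through the rule table")
}

# Filter-then-scan oracle for windowed BEC selection: plain loops over
# the observation vectors.
oracle_select <- function(dates, counts, enrol, mode, years = NULL) {
  keep_date <- c()
  keep_count <- c()
  for (i in seq_along(dates)) {
    if (dates[i] > enrol) next
    if (mode == "lookback" && dates[i] < enrol - years * 365.25) next
    keep_date <- c(keep_date, dates[i])
    keep_count <- c(keep_count, counts[i])
  }
  if (length(keep_count) == 0) {
    return(list(value = NA_real_, n = 0L))
  }
  if (mode == "latest") {
    best_date <- max(keep_date)
    best <- -Inf
    for (i in seq_along(keep_date)) {
      if (keep_date[i] == best_date && keep_count[i] > best) {
        best <- keep_count[i]
      }
    }
  } else {
    best <- -Inf
    for (v in keep_count) if (v > best) best <- v
  }
  list(value = as.numeric(best), n = length(keep_count))
}

# Single-patient cohort with an arbitrary BEC history and flag pattern.
make_patient_cohort <- function(bec_counts, bec_dates,
                                enrolment = as.Date("2020-01-01"),
                                on_anti_il5 = FALSE, maintenance_ocs = FALSE,
                                nasal_polyps = FALSE, feno_ppb = 10,
                                age_at_diagnosis = 10, age_at_enrolment = 50,
                                id = "P1") {
  eos_cohort(
    patients = tibble::tibble(
      patient_id = id, enrolment_date = enrolment,
      on_anti_il5 = on_anti_il5, maintenance_ocs = maintenance_ocs,
      nasal_polyps = nasal_polyps, feno_ppb = feno_ppb,
      age_at_diagnosis = age_at_diagnosis,
      age_at_enrolment = age_at_enrolment
    ),
    bec = tibble::tibble(
      patient_id = rep(id, length(bec_counts)),
      obs_date = bec_dates, count = as.integer(bec_counts)
    )
  )
}

`%||%` <- rlang::`%||%`
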