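---
title: "Grading the eosinophilic phenotype in difficult asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading the eosinophilic phenotype in difficult asthma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eosgradient)
```

## The problem

Severe and difficult-to-treat asthma is heterogeneous, and the decision
to start an eosinophil-targeting biologic hinges on whether a patient's
disease has an eosinophilic background. The obvious biomarker — the
blood eosinophil count (BEC, cells/µL) — is unstable: high oral and
inhaled corticosteroid burden suppresses circulating eosinophils, so a
single snapshot taken at clinic enrolment can mask an underlying
eosinophilic phenotype. The International Severe Asthma Registry (ISAR)
consortium addressed this with a *gradient* rather than a binary call: a
decision table that combines BEC bands with clinical indices and assigns
each patient an ordinal probability grade from 0 ("unlikely
eosinophilic") to 3 ("most likely eosinophilic").

`eosgradient` implements that algorithm as a tested pipeline, extends it
with longitudinal windowing of historical BECs, classifies
induced-sputum granulocyte differentials into the standard four
phenotypes, and quantifies how blood-based grades and sputum snapshots
disagree. Because the registry datasets behind the published validation
are not deposited anywhere, the package also ships two kinds of
substitute data, both first-class code: a seeded synthetic cohort
generator, and deterministic fixture builders that reconstruct cohorts
from the published summary tables of the WATCH (Wessex AsThma CoHort of
difficult asthma) validation study.

## The decision table

Nine mutually exclusive rows, evaluated top to bottom:

| BEC band (cells/µL) | Condition                          | Grade | Criterion |
|---------------------|------------------------------------|-------|-----------|
| ≥ 300               | —                                  | 3     | `BEC_GE_300` |
| any (incl. missing) | on anti-IL-5 / anti-IL-5Rα therapy | 3     | `ANTI_IL5` |
| \[150, 300)         | maintenance OCS                    | 3     | `MID_OCS` |
| \[150, 300)         | ≥ 2 of {NP, FeNO > 25 ppb, adult onset} | 3 | `MID_T2_MULTI` |
| \[150, 300)         | exactly 1 of those T2 features     | 2     | `MID_T2_SINGLE` |
| \[150, 300)         | none of them                       | 1     | `MID_T2_NONE` |
| < 150               | maintenance OCS                    | 2     | `LOW_OCS` |
| < 150               | ≥ 1 T2 feature                     | 1     | `LOW_T2_ANY` |
| < 150               | none                               | 0     | `LOW_T2_NONE` |

Design choices that the published table leaves open, and how this
package resolves them:

* **Band boundaries.** The printed bands are "<150", "150–300", "≥300".
  300 is explicitly in the top band, so the middle band is half-open,
  `[150, 300)`, and 150 belongs to it by the same reading.
* **"Presence of >2 of the following" three features.** Read literally
  this means all three; but a patient with exactly two features would
  then fall to the "either … or" grade-2 row, and the source registry
  description speaks of at least two. The default is therefore **≥ 2 of
  3**, which also makes the rows mutually exclusive when "either" is
  read as "exactly one". The literal reading remains available through
  `grading_thresholds(t2_feature_count_for_grade3 = 3)`.
* **Criterion precedence.** BEC ≥ 300 and anti-IL-5 therapy both assign
  grade 3; the BEC row wins so that each patient matches exactly one row
  and the per-criterion counts partition the cohort (a requirement for
  reproducing published column totals).
* **Missing data.** A missing FeNO or diagnosis age resolves the
  corresponding flag to `FALSE` — the algorithm never claims a
  type-2 feature without evidence — and every resolution is reported
  with its patient id. FeNO elevation is strict (`> 25` ppb, so exactly
  25 is not elevated); adult onset is a diagnosis age of **≥ 18 years**,
  the conventional adult/childhood split, which the published grade
  comparisons (median diagnosis age 21.5 vs 6.5 years in the high and
  low groups) are consistent with. A patient with no eligible BEC and no
  anti-IL-5 therapy is *ungradable*: reported separately, never folded
  into a grade or a denominator.

## Longitudinal windowing

Grading runs at enrolment. A window spec decides which historical
observations may contribute:

* `latest` — the most recent pre-enrolment result only (ties on the day
  resolve to the higher count, consistent with the algorithm's bias
  toward detecting eosinophilia);
* `lookback` *k* years — the highest result in the closed interval
  `[enrolment − k·365.25 days, enrolment]`;
* `ever` — the highest pre-enrolment result on record.

Observations after enrolment are never eligible, in any mode: grading at
enrolment with post-enrolment data would leak information the clinic did
not have. The 365.25-day year is a deliberate, documented convention; no
calendar subtleties beyond it are modelled.

Because the eligible sets are nested (`latest` ⊆ any `lookback` ⊆
`ever` in the max they can produce) and the decision table is monotone
in BEC at fixed flags, the assigned grade is non-decreasing in window
width whenever both windows can grade the patient. Both halves of that
argument are tested exhaustively (grid over BEC 0–600 × all 32 flag
patterns against an independently coded rule table) and end-to-end on
simulated cohorts.

```{r}
cohort <- simulate_cohort(simulation_config(n_patients = 200, seed = 7))
sapply(list(latest = window_spec("latest"), ever = window_spec("ever")),
       function(w) {
         d <- grade_distribution(grade_cohort(cohort, w)$criterion_counts)
         d$pct[d$grade == 3]
       })
```

## Sputum granulocyte phenotypes

Induced-sputum differentials (percentages of non-squamous cells) are
partitioned at 2% eosinophils and 61% neutrophils, inclusive on the
high side exactly as conventionally printed: eosinophilic (≥2, <61),
mixed granular (≥2, ≥61), neutrophilic (<2, ≥61), pauci-granular
(<2, <61). The partition is verified at every 0.1% grid point of the
admissible simplex. Two derived definitions are used by the discordance
statistics: *sputum eosinophilia* means eosinophils at or above the 2%
cut (labels eosinophilic or mixed granular), and *neutrophilic airways
disease* means neutrophils at or above 61% (labels mixed granular or
neutrophilic).

## Reconstructing published cohorts

`fixture_from_criterion_counts()` and `fixture_from_crosstab()` turn a
printed summary table back into a gradable cohort: for each
decision-table row (or grade × phenotype cell) they emit the stated
number of patients whose single-observation BEC history, flags, and
canonical sputum differential are witnesses of exactly that row. Witness
constants (BEC 350 / 200 / 100 for the three bands; differentials 5/40,
5/70, 1/70, 1/40 for the four phenotypes) are interior points of their
regions — any interior point would do, and fixed constants make the
round-trip (`grade_cohort()` returning the input counts) exact to the
integer. This is what lets the full pipeline be validated against the
published WATCH grade distributions (grade 3: 45.0% under the latest
window, rising to 67.0%, 74.8% and 77.4% as the window widens to 5
years, 10 years and ever) and the sputum cross-tabulation (130
patients, 36% sputum-eosinophilic, 82.3% grade 3, with 46% of grade-3
patients lacking sputum eosinophilia and 25% of sputum-eosinophilic
patients also neutrophilic) without any access to patient-level
registry data.

One denominator caveat: the published validation text speaks of 471
patients, but every printed column of per-criterion counts sums to 500
and every printed percentage is consistent only with a denominator of
500 (e.g. 225/500 = 45.0%). The package therefore uses the column sum
as the gradable denominator. Likewise the claim that 70% of patients
were at least grade 2 under the snapshot window is inconsistent with
the printed column (324/500 = 64.8%); neither figure is used for
validation.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure a difficult-asthma registry
analysis assumes; its defaults are the package's standing study
conditions, documented here because no public registry publishes the
underlying distributions — they are informed choices, not fitted
values.

* **BEC process.** Per-patient baseline `lognormal(log 180, 0.85)`
  cells/µL; per-observation multiplicative noise `lognormal(0, 0.45)`;
  observation dates a homogeneous process at 1.5/year over 15 years
  pre-enrolment (at least one observation, so every simulated patient is
  gradable). Patients on maintenance OCS (prevalence 0.30) have every
  count multiplied by a suppression factor of 0.55 — the masking
  mechanism. Exacerbation spikes at 1/year, lasting 14 days, multiply a
  coinciding count by 2.5; with blood draws at 1.5/year this yields
  occasional captured spikes per patient, which is what makes the
  highest-ever window so much more sensitive than the snapshot.
* **Clinical features.** Anti-IL-5 therapy 0.08, nasal polyps 0.35,
  adult onset 0.55; FeNO `lognormal(log 20, 0.8)` ppb. Flags are drawn
  independently by default — a simplification; a shared latent type-2
  factor that jointly raises baseline BEC, FeNO and the nasal-polyp
  propensity is implemented (`latent_t2_sd`) but off by default, since
  no published joint distribution supports a particular correlation
  strength.
* **Sputum.** A 26% subcohort, phenotype mixture weighted
  0.36/0.12/0.13/0.35 (eosinophilic / mixed / neutrophilic / pauci),
  with (eos, neut, other) cell fractions drawn from per-component
  Dirichlet distributions whose means sit inside the component's
  region.

The BEC parameters were set, once, so that the default cohort's grade-3
fraction lands near the published gradient endpoints (about 45% under
the latest window and about 77% under ever — a 2000-patient draw gives
45.4% and 78.7%). That is a design target for realism of the generator,
not an acceptance claim: the table-reproduction checks above use the
deterministic fixtures, never the simulator.

What the simulator deliberately does **not** model: eosinophil
depletion dynamics under biologic therapy, time-varying OCS exposure,
informative observation timing (more blood draws when exacerbating),
measurement error in FeNO, and within-patient sputum phenotype
instability. Passing tests on simulated cohorts therefore demonstrate
the pipeline's logic — monotonicity, masking, partition — not fidelity
to any real registry's joint distribution.

## Group comparisons

`compare_groups()` contrasts grade ≥ 2 against grade 0 patients
(grade 1 excluded, matching how the published comparisons are framed):
medians with a two-sided Wilcoxon rank-sum test for continuous
variables, proportions with a chi-squared test — switching to Fisher's
exact test when any expected cell is below 5 — for binary ones, and no
multiplicity correction. The tests are intentionally off-the-shelf: the
published analysis names no test, and these match the
median/proportion-style reporting. An empty group yields
`computable = FALSE` rows rather than an error. Real-cohort p-values
are not reproducible (the patient-level data are unavailable), so this
operation is exercised on synthetic cohorts only, including a
200-replicate power check on a 15-year median age shift.

## Numerical conventions and problem sizes

Table percentages are reported to one decimal place and derived
discordance statistics to the nearest whole percent, matching the
conventions of the tables they reproduce. Rounding uses R's `round()`
(banker's rounding); none of the reproduced quantities sits on a
half-percent boundary, so the convention is immaterial to them. The
test suite's standing problem sizes: the exhaustive rule-table check
runs BEC 0–600 × 32 flag patterns (19,232 cases); the windowed-selection
oracle runs 10,000 randomized histories; the monotonicity and masking
suites each run 200 seeded cohorts of 500 patients; the sputum partition
is checked at 0.1% resolution (~0.5M grid points).

## Limitations

The gradient is a probability ordering, not a calibrated probability;
nothing here predicts treatment response. The reconstruction fixtures
reproduce published *marginal* tables exactly but carry no
patient-level covariance, so they cannot support covariate analyses.
The simulator's defaults are labelled guesses and should be overridden
when registry-specific information exists.
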