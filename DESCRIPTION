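Package: eosgradient
Title: Eosinophil Gradient Phenotyping for Difficult Asthma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the International Severe Asthma Registry (ISAR)
    eosinophil gradient algorithm as a reusable phenotyping pipeline for
    difficult/severe asthma cohorts. A rule-based decision table assigns
    each patient an ordinal grade 0 (unlikely eosinophilic) to 3 (most
    likely eosinophilic) from blood eosinophil count bands combined with
    clinical features (anti-IL-5 therapy, maintenance oral corticosteroids,
    nasal polyps, elevated FeNO, adult-onset asthma). Includes longitudinal
    windowed selection of historical blood eosinophil counts (latest,
    k-year lookback, or highest-ever), induced-sputum granulocyte phenotype
    classification at the 2% eosinophil / 61% neutrophil cuts, cohort-level
    summaries with grade-by-sputum cross-tabulation and discordance
    statistics, a seeded synthetic cohort generator, and deterministic
    fixture builders that reconstruct published registry summary tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
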