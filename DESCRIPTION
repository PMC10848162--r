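Package: ibmfs
Title: Phenotype-First Triage of Inherited Bone Marrow Failure Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine for the early clinical suspicion of inherited bone
    marrow failure syndromes (IBMFS) from structured patient records. Records
    combine HPO-coded phenotype features, longitudinal complete blood counts,
    a transfusion log, screening laboratory results and family/prenatal
    history. The package grades cytopenias against pediatric thresholds,
    detects hereditary-suspicion "beacons" (consanguinity, endogamy, isonymy,
    familial hematologic disease, growth restriction, physical anomalies),
    applies per-syndrome suspicion rules for dyskeratosis congenita,
    Diamond-Blackfan anemia, Shwachman-Diamond syndrome, thrombocytopenia with
    absent radii and severe congenital neutropenia, flags Fanconi-anemia
    referral patterns, and falls back to an undefined-IBMFS label. Cohort-level
    summaries, group comparisons, a deterministic 48-patient reference cohort
    and a seeded synthetic-cohort simulator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
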