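Package: steroidror
Title: Disproportionality Analysis of Steroid-Associated Thrombosis in
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection of
    thrombotic adverse events among drugs carrying a steroid backbone, built
    around FAERS-style quarterly report tables. Covers report ingestion and
    deduplication, monotherapy filtering, SMARTS-based steroid cohort
    selection, SMQ-scoped preferred-term aggregation, reporting odds ratios
    with Haldane continuity correction and Fisher exact testing, volcano-plot
    screening, stratified and class-level summaries, and principal component
    analysis with Ward clustering of drug-by-event signal profiles. Includes
    a synthetic spontaneous-report generator with closed-form expected
    contingency tables so every stage is testable without access to FAERS.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ape,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
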