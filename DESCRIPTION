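Package: vsaudit
Title: Guideline-Concordance Audit of EGFR and Proteomic Test Utilization in NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patient-level audit pipeline for biomarker test utilization and
    erlotinib prescribing in non-small cell lung cancer (NSCLC). Provides a
    cohort data model for EGFR mutation testing, serum proteomic (VeriStrat)
    testing and erlotinib dispensing events; a first-match rules engine that
    codes each testing and treatment decision green (concordant), yellow
    (questionable or under-documented) or red (clear departure) against the
    recommended testing algorithm; timing and end-of-life metrics; a
    cost-of-care model with configurable unit costs; a deterministic fixture
    cohort plus a seeded stochastic cohort simulator for property testing; and
    report assembly with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    purrr,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
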