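Package: thyverify
Title: Diagnostic Performance of Thyroid Molecular Classifiers Under
    Partial Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating binary thyroid molecular classifiers in
    real-world cohorts where surgical histopathology (the reference standard)
    is observed only for a test-result-dependent subset of nodules. Implements
    cohort ingestion and validation for nodule-level data, exact small-sample
    statistics (Clopper-Pearson intervals, Fisher's exact test, Pearson
    chi-square), Bayes-theorem imputation of unverified test-negative nodules
    from an externally established sensitivity, naive and verification-adjusted
    performance metrics, counterfactual surgery-avoidance accounting, and a
    synthetic cohort generator for studying verification bias by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
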