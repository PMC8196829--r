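Package: pharmacotype
Title: Ex Vivo Pharmacotyping of Patient-Derived Tumor Organoids
Version: 0.1.0
Authors@R: person("Pharmacotype", "Maintainers", email = "maintainers@pharmacotype.org", role = c("aut", "cre"))
Description: Pipeline for ex vivo drug-response profiling ("pharmacotyping") of
    patient-derived organoid (PDO) libraries. Converts two-signal cytotoxicity
    plate-reader luminescence into percent viability, integrates ten-point
    dose-response curves into trapezoidal AUC on a log10-dose axis, partitions
    per-drug AUC vectors into high/intermediate/low responder classes with an
    exact Jenks natural-breaks (Fisher optimal 1-D) classifier, combines
    per-drug responder scores into a regimen prediction score (and a
    hard-margin linear SVM alternative), and evaluates cohorts against
    radiologic outcome: pharmacotyping efficacy, prediction accuracy, exact
    Fisher tests, Mann-Whitney comparisons, and Kaplan-Meier progression-free
    survival with log-rank tests. Ships a synthetic plate/cohort generator with
    known ground truth and a deterministic cohort fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
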