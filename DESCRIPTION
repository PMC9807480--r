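Package: mbrisk
Title: Clinico-Molecular Risk Stratification for Non-WNT/Non-SHH Medulloblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Arm-level copy-number and whole-chromosomal aberration (WCA)
    calling from binned log2-ratio profiles, rule-based clinical and
    clinico-molecular risk classification of Group 3/4 medulloblastoma, and a
    survival-model comparison framework (Cox regression with craniospinal
    irradiation as a time-dependent covariate, incident/dynamic time-dependent
    ROC AUC, inverse-probability-of-censoring-weighted Brier curves and
    integrated Brier score, bootstrap cross-validation, frozen-model external
    validation). Includes a calibrated synthetic cohort generator so the whole
    pipeline can be exercised and tested without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
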