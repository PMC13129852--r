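Package: metabopanel
Title: Machine-Learning-Assisted Plasma Metabolomics Biomarker Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for untargeted LC-MS plasma metabolomics
    biomarker discovery and validation: peak-table ingestion with internal-
    standard normalization and QC-based filtering, random-subspace random-forest
    consensus feature prioritization, univariate triage (volcano statistics,
    per-feature ROC AUC), OPLS-DA with cross-validated Q2 and label-permutation
    testing, MS1/MS2 annotation matching, and an interpretable logistic-
    regression metabolite panel with stratified and covariate-adjusted
    evaluation. Ships a synthetic-cohort generator with planted ground truth so
    every stage is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
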