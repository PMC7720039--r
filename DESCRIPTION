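Package: pancanproteo
Title: Downstream Analysis of Pan-Cancer DIA Proteome Quantification Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the downstream analysis
    stages applied to data-independent-acquisition (DIA) protein
    quantification matrices from multi-cancer tissue cohorts: replicate and
    per-sample quality control with a five-criterion qualification rule,
    per-cancer quantifiability filtering and two-branch missing-value
    imputation, detection of universally expressed (housekeeping) proteins,
    tissue-enrichment classification from pairwise tissue comparisons,
    tumor-versus-normal differential abundance with Benjamini-Hochberg
    correction, cross-cancer aggregation and protein-group clustering, and
    annotation-driven filtering for druggable and cancer/testis-antigen
    candidates. Includes a synthetic-cohort generator with machine-readable
    planted ground truth so every stage can be validated against a known
    answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
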