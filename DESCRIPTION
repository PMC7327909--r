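Package: spitzsig
Title: Differential Expression, Pathway Enrichment and a Stability-LASSO
    Malignancy Signature for NanoString Counts from Spitzoid Neoplasms
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible analysis pipeline for NanoString nCounter
    PanCancer panel count data from Spitzoid melanocytic neoplasms
    (Spitz nevi, atypical Spitz tumors, malignant Spitz tumors).
    Implements total-library-size normalization with voom-style
    precision weights, empirical-Bayes moderated t-statistics for
    two-group contrasts, competitive gene-set enrichment with a
    variance-inflation correction for inter-gene correlation, and a
    repeated cross-validation stability-LASSO procedure that yields a
    weighted gene signature and a per-sample malignancy score on a
    0-1 scale with a 0.4 low/high cut. Includes a negative-binomial
    synthetic cohort generator with planted effects so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
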