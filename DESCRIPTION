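Package: bactsig
Title: Sparse Host Gene-Expression Signatures for Ruling Out Bacterial
    Respiratory Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives parsimonious whole-blood gene-expression signatures
    that discriminate any-bacterial from nonbacterial acute respiratory
    infection. Provides the full analysis pipeline: counts-per-million
    normalisation and quality-control filtering (low-expression genes,
    PCA sample outliers, batch-variance genes), a simplified
    negative-binomial Wald differential-expression test with
    Benjamini-Hochberg correction and a leave-one-batch-out consistency
    analysis, a hard-thresholded mostly-relaxed LASSO-constrained
    logistic regression tuned by nested leave-one-batch-out
    cross-validation, and sensitivity-anchored classification thresholds
    with negative predictive value reported over a prevalence range.
    Includes a negative-binomial cohort simulator with planted sparse
    signatures, batch effects and unequal library sizes for validating
    every stage against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    DESeq2
Config/testthat/edition: 3
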