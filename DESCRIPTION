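Package: covDEG
Title: Coverage-Based Multiclass Differential Expression and Signature
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates multiple gene-expression series into one
    quantile-normalized matrix, extracts multiclass differentially
    expressed genes with a pairwise-contrast coverage (COV) statistic
    combined with log-fold-change and moderated-t p-value thresholds,
    ranks genes by minimum-redundancy maximum-relevance (mRMR), and
    assesses gene signatures with a multi-classifier stratified
    cross-validation harness and a Type III factorial ANOVA over
    pipeline hyperparameters. Includes a synthetic multi-series,
    multi-class expression simulator with planted pairwise effect
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    car,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
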