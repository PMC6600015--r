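Package: drugOmics
Title: Multi-Omic Prediction of Drug Sensitivity in Cancer Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Benchmarking framework for comparing genomic, transcriptomic and
    proteomic data as predictors of drug sensitivity in cancer cell-line
    panels. Summarises dose-response viability screens as mean-viability AUC,
    fits partial least squares (PLS and multi-output PLS2), regression-tree,
    elastic-net/lasso and maximum-correlation models under a leakage-free
    repeated nested cross-validation protocol, calibrates significance with
    permutation null distributions and Benjamini-Hochberg adjustment, and
    supports multi-omic early/late integration and cross-tissue transfer
    benchmarking (including equal-sample-size "cross fair" resampling).
    Includes a seeded synthetic panel generator with planted ground truth
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    rpart,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
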