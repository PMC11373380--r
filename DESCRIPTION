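Package: pcnt
Title: Hybrid PC-Constrained Continuous Causal Discovery for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Causal structure and effect-size estimation from observational
    gene-expression matrices. Runs the PC-stable constraint-based search
    (Gaussian conditional-independence tests, v-structure orientation, Meek
    rules) to obtain a CPDAG, converts the CPDAG into a hard edge-constraint
    mask, and solves the NOTEARS continuous acyclicity-constrained least-squares
    program restricted to that mask, yielding a weighted directed acyclic graph
    with signed linear effect sizes. Includes bootstrap aggregation of edge
    estimates, graph evaluation metrics (structural Hamming distance, oriented
    F1, orientation accuracy, regulator prediction AUROC/AUPRC, coefficient
    correlation against a weighted ground truth), a ground-truth subsampling
    benchmark protocol, and a synthetic generator of sparse regulator-target
    networks with linear structural-equation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
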