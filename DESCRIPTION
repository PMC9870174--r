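Package: psnmine
Title: Patient Similarity Network Mining for Health Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers subject-similarity networks from binary health-survey
    data and mines them for latent subject groups. Provides a synthetic
    survey generator with planted cluster structure, curation of raw survey
    tables (missingness pruning, one-hot encoding, correlation filtering),
    stepwise wrapper feature selection scored by ROC AUC, four network
    inference methods (minimum-connectivity k-nearest-neighbour graphs,
    Meinshausen-Buhlmann neighbourhood selection, the graphical lasso, and
    correlation thresholding), four graph clustering methods (Louvain,
    Leiden, and resilience-based node-removal clustering driven by vertex
    attack tolerance or integrity), five internal cluster validity indices
    with a points-based ranking scheme, and cluster composition profiling
    with small-cluster suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    cluster,
    withr,
    xml2
Config/testthat/edition: 3
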