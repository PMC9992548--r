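Package: clpnet
Title: Contemporaneous and Cross-Lagged Symptom Networks for Two-Wave
    Ordinal Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimation and comparison of regularized partial-correlation
    (Gaussian graphical) models for ordinal symptom data measured on the
    same items at two occasions, as used in psychopathology network
    analysis of anxiety, depression and loneliness scales.  Provides a
    nonparanormal (rank-Gaussianizing) transform, a graphical lasso with
    rotation-information-criterion regularization selection, spinglass and
    weighted clique-percolation community detection, (bridge) expected
    influence centralities and node predictability, a permutation network
    comparison test, case-dropping correlation-stability analysis, and a
    lasso cross-lagged panel network with nodewise in-/out-prediction and
    path-model fit indices.  A synthetic two-wave ordinal panel generator
    with known partial-correlation and cross-lagged ground truth supports
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
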