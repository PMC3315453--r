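Package: netcrit
Title: Critical and Exceptional Edges in Gene Function Prediction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates how gene function is encoded in undirected gene
    networks using neighbor-voting guilt by association with cross-validated
    average precision, and quantifies how concentrated that information is in
    individual edges. Provides exhaustive leave-one-edge-out criticality
    scans, per-edge exceptionality scores, prediction of exceptional edges
    from annotation overlap alone, node-degree network pruning with
    degree-distribution diagnostics and prediction-rank concordance, and a
    random-network null simulation framework (calibration, screening for
    high-performing random networks, and recurrent-edge analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Network, GraphAndNetwork, FunctionalPrediction, GeneFunction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
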