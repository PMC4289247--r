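Package: crossclust
Title: Cross-Species Gene Module Detection on Coupled Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects gene modules jointly across multiple species by optimizing
    a q-state Potts cost function over a multi-layer network: per-species
    (optionally signed) co-association layers joined by weighted orthology
    links, with a coupling constant controlling the trade-off between
    within-species modularity and cross-species ortholog co-assignment.
    Optimization uses heat-bath simulated annealing with geometric cooling;
    repeated runs are aggregated into a co-appearance matrix from which
    conserved and species-specific modules are extracted by stringent
    thresholding. Includes rank-based signed co-expression network
    construction from expression matrices, a brute-force ground-state oracle
    for small instances, module evaluation machinery (GO inverse-document-
    frequency cosine similarity, weighted-network modularity, metagene
    recovery, ortholog-enrichment and regulator-sharing tests, clustering
    overlap, ncRNA-to-module mapping), and a synthetic-data generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    methods,
    parallel,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
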