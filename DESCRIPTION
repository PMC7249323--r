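Package: scHierEval
Title: Hierarchy-Aware Evaluation of Single-Cell Clustering Results
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: External cluster-validity metrics for single-cell RNA-seq that
    account for the hierarchical relationships between reference cell types.
    Implements the weighted Rand index (wRI) with weighted positive and
    negative predictive values, and the weighted normalized mutual
    information (wNMI) built on a structured entropy driven by a reference
    dendrogram, alongside their classical counterparts (RI, ARI, MI, NMI).
    Weight matrices and the reference tree can be supplied directly or
    estimated from a labelled expression matrix via mean cell-type profiles.
    A synthetic hierarchical-population generator with known ground truth
    supports benchmarking and testing, and a command-line interface exposes
    the metrics, estimation, and simulation routines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
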