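Package: diffggm
Title: Differential Network Analysis via Inference of Gaussian Graphical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-sample differential network analysis for gene expression data.
    Estimates each condition's Gaussian-graphical-model precision matrix
    entrywise by scaled-lasso node-wise regression with asymptotic standard
    errors, tests equality of every precision-matrix entry between the two
    conditions with an asymptotically normal statistic, and recovers the
    differential network by direct thresholding of the statistics with false
    discovery rate control. Includes a simulator of paired hub, scale-free and
    random graphical models with controlled heterogeneity, and a replication
    harness scoring support recovery by AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
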