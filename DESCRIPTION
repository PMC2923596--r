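Package: ppinet
Title: Information-Theoretic Characterisation and Comparison of Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising undirected interaction networks (such as
    protein-protein interaction networks) by their degree statistics and
    normalised degree-degree correlations, for quantifying their
    information-theoretic complexity relative to degree-matched random-graph
    ensembles, for measuring a symmetrised Kullback-Leibler distance between
    networks, for drawing unbiased degree-preserving null models by edge-swap
    Markov chain Monte Carlo, and for distance-based hierarchical clustering
    and sub-sampling robustness experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
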