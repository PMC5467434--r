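Package: dirtopo
Title: Topological Analysis of Directed Networks and Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the topology of directed networks such as
    synaptic connectomes. Builds directed flag complexes, enumerates directed
    cliques (simplices) and their maximal members, computes mod-2 simplicial
    homology (Betti numbers, Euler characteristic), measures net directionality
    of motifs, and generates density-matched control networks (uniform random,
    pruned-candidate, and distance-preserving shuffles). A structure-function
    layer bins spike trains into peri-stimulus time histograms, computes
    normalised cross-covariance matrices, derives time series of
    transmission-response graphs, and relates pairwise spike correlations to
    simplex membership and position. Includes generators for synthetic
    geometric circuits and correlated spike trains, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
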