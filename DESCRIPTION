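Package: mitonet
Title: Percolation and Complexity Analysis of Mitochondrial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the structure of mitochondrial networks from
    fluorescence images using tools from network and percolation theory.
    Images are binarized over a range of intensity thresholds, reduced to
    one-pixel skeletons, and decomposed into clusters and segments; from
    these the package computes cluster-mass distributions and their
    power-law exponents, mass entropy and the critical binarization
    threshold, box-counting fractal dimension, Lempel-Ziv complexity
    z-scores, and finite-size scaling of the giant cluster. A stochastic
    agent-based simulator of tip-to-tip and tip-to-side fission/fusion
    kinetics (Gillespie dynamics over a population of dimers) generates
    the model's phase diagram in the space of relative fusion rates, and
    measured network observables can be inverted onto that diagram to
    classify a network as subcritical, critical or supercritical. A
    synthetic-image generator renders simulated networks as
    pseudo-confocal micrographs so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
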