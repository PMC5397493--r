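Package: ringstate
Title: Orientation Detection in a Depressing Ring Network across Cortical
    Functional States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic simulation and decoding pipeline for a firing-rate
    ring model of a primary visual cortex orientation hypercolumn with
    short-term synaptic depression and Ornstein-Uhlenbeck input noise.
    Emulates cortical functional states by jointly varying neurotransmitter
    release probability and baseline depolarization at a fixed stimulus-free
    mean firing rate, presents brief oriented stimuli, decodes the
    represented orientation with exact and sparse Poisson-spiking
    population-vector readouts, and sweeps states to locate the release
    probability giving the most precise orientation detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
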