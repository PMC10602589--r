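Package: contdecide
Title: Continuous Perceptual Decision-Making: Stimulus Simulation, Integration
    Kernels, Leaky Accumulation and Deconvolutional EEG Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying evidence accumulation in continuous,
    trial-free perceptual decision tasks. Generates condition-structured
    random-dot-motion coherence streams with experimenter-controlled noise
    and scores buttonpresses under a points-based reward rule; estimates
    reverse-correlation integration kernels and fits regularised
    exponential-decay models to them; simulates an Ornstein-Uhlenbeck leaky
    accumulator agent and maps its reward landscape over leak and threshold;
    builds time-expanded deconvolutional design matrices and estimates
    temporal response functions from continuous multichannel recordings by
    ordinary least squares; and provides cluster-based permutation tests and
    across-subject brain-behaviour rank correlations for group inference.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    methods,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
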