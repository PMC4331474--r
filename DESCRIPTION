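Package: spikebee
Title: Spiking Neuron Pattern Classification Trained by Artificial Bee
    Colony Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains a single Izhikevich regular-spiking neuron as a
    firing-rate pattern classifier. Each input pattern is converted to a
    constant input current by a synaptic weight vector, the neuron is
    simulated by forward-Euler integration, and the class is decided by
    the nearest per-class average firing rate. The synaptic weights are
    optimized with the artificial bee colony (ABC) metaheuristic
    (employed, onlooker and scout phases with limit-based abandonment).
    Includes synthetic dataset generators (Gaussian clusters and
    planted-weights constructions), a repeated stratified train/test
    experiment protocol with t-distribution confidence intervals, broom
    style tidiers and ggplot2 autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
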