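Package: rsoftplus
Title: Refractory SoftPlus Transfer Functions and Empirical Neural Mean-Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures single-neuron transfer functions by simulating leaky
    integrate-and-fire, Izhikevich, and Hodgkin-Huxley neurons under balanced
    Poisson synaptic input, fits the four-parameter Refractory SoftPlus
    transfer function to the measured curves, and uses the fitted function to
    build mean-field models of recurrently connected populations: equilibrium
    firing rates via a consistency condition, saddle-node bifurcation scans in
    the in-degree, first-order firing-rate dynamics under time-varying
    stimuli, and validation against full spiking-network simulations
    including finite-size fluctuation scaling and practical-stability
    experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
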