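Package: hspnet
Title: Spiking Network Simulation of Homeostatic Structural Plasticity and Synaptic Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of inhibition-dominated leaky
    integrate-and-fire networks in which excitatory-to-excitatory synapses are
    created, pruned and rewired by calcium-driven structural plasticity growth
    rules (linear, zero-Gaussian and biphasic-Gaussian), and synaptic weights
    are regulated by a calcium-driven multiplicative homeostatic scaling rule.
    Includes growth, perturbation (fold-of-original-intensity), silencing and
    rescue protocols, parameter sweeps, and the connectivity and firing-rate
    metrics needed to quantify homeostatic rewiring: block-averaged structural
    and effective connectivity, synapse counts, and deviation-from-setpoint
    areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
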