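Package: liquidens
Title: Ensemble Liquid State Machines for Spiking Reservoir Computing
Version: 0.1.0
Authors@R:
    person("Janek", "Doering", email = "jdoering@example.org",
           role = c("aut", "cre"))
Description: Tools for studying why splitting one large spiking reservoir into
    an ensemble of small, mutually unconnected reservoirs improves class
    discrimination in liquid state machines. Provides a clock-driven simulator
    of conductance-based leaky integrate-and-fire neurons with excitatory and
    inhibitory populations, random sparse topology construction under a fixed
    neuron budget, Poisson and probability-matrix spike encoders, kernel
    quality metrics (pairwise separation, rank-based separation and
    generalization, within/between-class scatter and the discriminant ratio),
    trained softmax readouts in single- and multiple-readout configurations,
    seeded synthetic data generators, and experiment drivers reproducing the
    ensemble-size trend analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
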