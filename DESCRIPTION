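Package: analognet
Title: Desk-Scale Software Twin of an Accelerated Analog Neuromorphic Core
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the analog core of an accelerated mixed-signal
    neuromorphic chip at desk scale: adaptive exponential integrate-and-fire
    (AdEx), leaky integrate-and-fire and integrator neuron dynamics with
    hardware-style feature switches, multi-compartment neuron graphs with
    plateau-type dendritic spikes, a quantized address-matched synaptic
    crossbar with graded spikes and an analog matrix-multiply mode,
    per-synapse spike-timing correlation sensors with a programmable
    row-parallel plasticity engine, homeostatically regulated recurrent
    reservoirs and their autocorrelation-time analysis, fixed-pattern-noise
    modelling with automated measurement-based calibration, event-based
    adjoint gradients for hybrid dynamical systems, and surrogate-gradient
    training from sampled membrane traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
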