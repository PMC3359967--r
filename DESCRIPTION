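Package: drgexcite
Title: Conductance-Based Models and Dynamical Analysis of Sensory Neuron
    Hyperexcitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical-systems analysis of minimal
    Morris-Lecar-type models of dorsal root ganglion (DRG) neuron
    excitability. Implements a family of two- and three-dimensional
    conductance-based model variants (standard, slow sodium-channel
    inactivation, spike-frequency adaptation, fast sodium-inactivation, and
    an "ungrouped" variant splitting the slow current into delayed-rectifier
    and subthreshold components), fixed-step Euler and Euler-Maruyama
    integration with additive membrane noise, fixed-point and bifurcation
    analysis with Hopf detection and sub/supercritical classification,
    phase-plane tools (nullclines, quasi-separatrix), fast-slow dissection
    of elliptic bursting, and feature extraction (spike detection, response
    classification, rheobase bisection, membrane potential oscillation
    power spectra, burst statistics, parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
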