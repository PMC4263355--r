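Package: oscgate
Title: Oscillation-Gated Synchrony Propagation in Spiking Networks with
    Nonlinear Dendrites
Version: 0.1.0
Authors@R:
    person("Ripple", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates feed-forward structures embedded in (or isolated from)
    recurrent conductance-based integrate-and-fire networks with linear
    (additive) or nonlinear (dendritic-spike) synaptic integration, driven by
    Poisson background input and balanced or unbalanced oscillatory input from
    a virtual population. Provides generators for Erdos-Renyi topologies with
    embedded feed-forward subnetworks and four conduction-delay models
    (homogeneous, uniform, log-normal with fixed mode, hippocampal
    distance-based), a fast C++ simulation engine, a signal-to-noise
    propagation detector, the binomial iterated map of layerwise synchrony with
    fixed-point and tangent-bifurcation analysis, critical-coupling searches,
    resonance and locking scans, and frequency-gated routing experiments
    between feed-forward networks with distinct delay means.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
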