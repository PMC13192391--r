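Package: plateaukit
Title: Biophysics of Plateau-Potential Termination in a Single-Compartment Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a single-compartment conductance-based model of CA1
    pyramidal-cell plateau potentials (GHK-flux voltage-gated calcium channel
    with calcium-dependent inactivation, SK-type calcium-activated potassium
    current, passive leak, exponential-decay inhibitory synapse, submembrane
    calcium pool) and provides the analysis pipeline for inhibitory plateau
    termination: all-or-none termination-threshold search, IPSG timing and
    amplitude-by-decay-tau sweeps, membrane-current dissection, steady-state
    fixed-point and threshold-branch tracking, dynamic-threshold estimation
    against IPSP dV/dt, conductance grid-search calibration, and a synthetic
    noisy-recording generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
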