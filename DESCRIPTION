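Package: mfcircuit
Title: Two-Ensemble Mean-Field Cortical Circuit Simulation and
    Input-Output Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a reduced cortical circuit model consisting of two
    recurrent excitatory ensembles coupled through effective global
    inhibition, driven by transient pulse stimuli, slow sinusoidal
    background input, and Ornstein-Uhlenbeck synaptic noise.  Provides the
    stimulus protocols and excitation-inhibition parameter sweeps used to
    map cross-suppression regimes, slow-oscillation propagation, and
    sensory-response fidelity, together with the input-output analysis
    metrics (trial-to-trial reliability, stimulus-response
    cross-correlation amplitude and decay, time to half-maximal cumulative
    response, band power) for model traces and for surrogate LFP/MUA
    recordings generated by a built-in synthetic-session module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
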