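Package: mcescape
Title: Conductance-Based Modelling and Analysis of the Mauthner-Cell Startle
    Escape Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-neuron conductance-based (modified Morris-Lecar)
    model of the zebrafish Mauthner-cell startle escape circuit, including
    dopaminergic (D1), GABAergic and glycinergic modulation, and runs in-silico
    receptor-blockade experiments under dominant-like and subordinate-like
    social-status presets. Also provides the accompanying analysis pipeline:
    swim-burst detection from field-potential traces, Mauthner-latency trial
    filtering, startle-probability tabulation with Boltzmann sigmoid fitting,
    and efficiency-corrected comparative delta-delta-Ct quantification of qPCR
    data, together with seeded synthetic-data generators carrying ground truth
    for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
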