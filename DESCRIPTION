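Package: hippogamma
Title: Hippocampal Network Simulation of Gamma-Band Entrainment Deficits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a four-population hippocampal microcircuit
    (pyramidal, basket, chandelier and calretinin-positive cells) built
    from multicompartment Hodgkin-Huxley neuron models with kinetic
    AMPA/NMDA/GABA-A synapses, drives it with periodic click trains at
    20/30/40 Hz, and summarises the simulated EEG by FFT band powers.
    Provides declarative lesion transforms (NMDA hypofunction, dendritic
    spine pruning, GABA-system dysregulation) and drug transforms for
    graded, combinatorial parameter sweeps; scalar illness and wellness
    metrics scored against the gamma-band (40 Hz) entrainment deficit;
    cluster detection on sweep grids; simulated-subject cohorts with
    mixed-model and factorial ANOVA plus hierarchical regression; and
    surrogate-signal generators for fast testing of the analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
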