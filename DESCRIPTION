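Package: burstlab
Title: Burst Generation and Control in a Reduced Layer-5 Pyramidal Cell Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conductance-based simulation of somatic spike-burst generation in a
    reduced layer-5 pyramidal cell. Builds a reduced branched morphology with an
    apical calcium hotspot, attaches Hodgkin-Huxley-style channels, AMPA/NMDA and
    GABA-A synapses and a single-pool calcium mechanism, and integrates the
    branched cable with an implicit (backward Euler) tree solver. Provides
    stochastic spatiotemporal synaptic input generators, burst detection and
    statistics (ISI grouping, intra-burst rate, delay-window metrics, burst-class
    rules), calcium-dependent synaptic plasticity (omega/eta rule), and scripted
    scan protocols for excitation timing, synapse-count grids, dendritic
    inhibition location/timing, and plasticity maps.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
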