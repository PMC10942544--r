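Package: hippocircuit
Title: Potential Connectomics and Spiking-Network Simulation for
    Hippocampal Neuron Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for building data-driven models of
    hippocampal circuits from neuron-type knowledge bases. Encodes the
    laminar distribution of axons and dendrites of each neuron type as
    digit strings over a 26-parcel registry, derives the directed
    potential connectome from axonal-dendritic overlap, estimates
    connection probabilities and contacts per connected pair from
    axonal lengths, inter-bouton distances and dendritic lengths,
    solves the neuron-type census from literature-style linear
    constraints by nonnegative least squares, and instantiates and runs
    spiking networks of single-compartment Izhikevich neurons coupled
    by Tsodyks-Pawelzik-Markram conductance synapses. Includes F-I
    curves, a reduced firing-pattern labeler, evolutionary-algorithm
    model fitting, band-filtered local-field-potential proxies, a
    deterministic CSV parameter-bundle dialect with per-field
    provenance flags, and a seeded synthetic knowledge-base generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
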