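Package: flybrainsim
Title: Connectome-Derived Spiking Network Models of the Drosophila Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds spiking network models from neuron skeleton morphologies
    and simulates them at the whole-brain scale. Reads SWC skeletons, computes
    morphometric features and classifies arbors as axonal or dendritic with a
    linear classifier, infers directed connections from axo-dendritic contact
    points under distance and relative-contact criteria (with ROC-based
    criterion tuning), estimates leaky integrate-and-fire membrane parameters
    from skeleton length, and integrates conductance-based network dynamics
    with AMPA, NMDA, GABA-A and acetylcholine receptors, short-term synaptic
    depression, and calibrated background noise. Includes structural and
    dynamical analyses (excitation-inhibition index, degree and contact
    distributions, hyperactivity detection, firing-rate distribution fitting,
    Fano factors), presynaptic-preserving network randomization, and synthetic
    skeleton and connectome generators for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
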