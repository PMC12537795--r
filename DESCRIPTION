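Package: mesocol
Title: Contextually Guided Feature Extraction in a Cortical Mesocolumn Model
Version: 0.1.0
Authors@R:
    person("Model", "Builder", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a two-stage model of feature extraction by neocortical
    columns in primary visual cortex. A difference-of-Gaussians LGN front end
    encodes image patches onto a hexagonal receptive-field lattice; a layer-4
    network with Hebbian afferent and anti-Hebbian lateral plasticity performs
    an RBF-like nonlinear transform; contextually predictable "canonical
    variates" are extracted by a multi-view generalized eigenproblem; and
    two-compartment layer-3 cells learn canonical features under contextual
    guidance from surrounding columns. Includes synthetic stimulus generators
    (pink noise, oriented textures, sinewave gratings), the full evaluation
    battery (F1/F0 ratios, orientation tuning half-widths, population
    discrimination angles, texture clustering), and a staged pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
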