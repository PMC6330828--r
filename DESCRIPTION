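Package: dgturnover
Title: Neuronal and Synaptic Turnover in a Sparse Dentate Gyrus Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a feedforward entorhinal cortex to dentate gyrus (DG) to
    CA3 network in which adult neurogenesis is modelled as competitive turnover
    of DG units. Binary context patterns with flip noise drive a randomly
    connected expansion layer whose sparseness is set by an activation
    threshold; a CA3 readout is trained by the Moore-Penrose pseudoinverse.
    Three turnover rules are provided: neuronal turnover by readout-weight
    magnitude, its multi-context generalization, and synaptic turnover with a
    linear stability transfer function. Includes the accompanying analysis
    stack: generalization error, signal-to-noise decomposition, context-bias,
    singular-value analysis of the population code, restricted-dimension
    readouts, and material-turnover accounting, plus preset experiments and
    parameter scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
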