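Package: striomap
Title: Quantification of Corticostriatal Inputs onto Reconstructed Striatal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping motor (M1) and sensory (S1) corticostriatal
    inputs onto single reconstructed striatal neurons. Represents neuron
    morphologies as rooted geometric trees read from SWC files, assigns
    candidate presynaptic puncta to a neuron by an edge-clearance rule,
    localizes each input by compartment (spine, shaft, soma) and geodesic
    distance from the soma, and summarizes input distributions, densities,
    and cross-channel nearest-neighbour clustering. Also extracts action
    potential features (half-height width, interspike intervals,
    instantaneous and maximal firing frequency, passive properties) from
    current-clamp sweeps to classify cells as spiny projection neurons or
    fast-spiking interneurons, reproduces the normality-gated statistical
    test selection used for group comparisons, and generates synthetic
    morphologies, puncta, and sweeps with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
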