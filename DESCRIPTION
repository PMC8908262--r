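Package: spikeprune
Title: Synaptic-Pruning Spiking Neural Networks for Few-Shot Digit
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulator and classifier built around a synaptic-pruning
    spiking neural network. Images on a 28x28 grid are rate-coded into
    spike trains over eight half-plane regions, fed through discrete-time
    integrate-and-fire layers with optional feedback inhibition, and
    trained per class with a firing-rate-difference plasticity rule whose
    weak synapses are pruned away, leaving sparse class-specific
    "information channels". A ten-network ensemble classifies by maximum
    output firing rate. Includes a synthetic stroke-digit generator, an
    IDX (MNIST container) reader/writer, and seeded parameter-sweep
    runners.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
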