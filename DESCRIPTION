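Package: htmseq
Title: Sequence Memory with Active Dendrites and Sparse Distributed
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a hierarchical temporal memory (HTM) sequence
    memory: networks of mini-columns whose cells carry dendritic segments
    acting as threshold coincidence detectors over permanence-weighted
    synapses. Provides the exact combinatorics of false matches for sparse
    distributed representations (hypergeometric tail probabilities, noise
    tolerance, per-neuron pattern counts, network transition capacity),
    deterministic symbol-to-SDR encoders and a synthetic generator of
    high-order symbol streams, the online Hebbian structural-plasticity
    learning rules (segment growth, permanence reinforcement and decay),
    lesioning, and the simulation protocols for online high-order
    learning with a mid-run sequence swap and for robustness to cell
    death.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
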