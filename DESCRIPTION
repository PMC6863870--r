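Package: lineagecircuits
Title: Progenitor Lineage, Transcriptomic Identity and Cortical Circuit Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain linking embryonic progenitor pool to cortical
    neuron identity and connectivity. Provides median-absolute-deviation
    quality control and log2-CPM normalization for single-cell RNA-seq
    count matrices, reference-atlas bootstrap classification of Patch-seq
    cells with a vote-fraction certainty score, directed connectivity
    tallies with out-of-class bias statistics and exact tests (Fisher
    2x2, Wilcoxon signed-rank), EPSP feature extraction from averaged
    patch-clamp sweeps, and a synthetic-data module that emulates the
    statistical structure of all inputs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
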