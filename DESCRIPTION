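Package: cmapkit
Title: Processing and Connectivity Analysis of Targeted L1000-Style
    Transcriptional Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete processing and query stack for bead-based
    (Luminex / L1000-style) targeted transcriptional profiling screens
    with a 1:1 barcode-to-gene panel.  Raw bead fluorescence is carried
    through five data levels: median fluorescence intensity per barcode,
    invariant-set calibration and per-plate quantile normalization,
    gene-wise robust z-scores, and correlation-weighted replicate
    collapse into signatures.  Per-signature quality metrics (replicate
    correlation, signature strength, transcriptional activity score) are
    computed, probe fidelity can be validated by recall against a
    reference RNA-seq panel, and up/down gene-set queries are scored
    against signature collections with weighted connectivity scores,
    normalized scores, and signed tau percentiles, aggregated to
    median-tau mimic and reverse rankings.  A seeded simulator generates
    bead-level screens, reference expression panels, and touchstone
    collections with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    cluster,
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
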