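Package: chromstripe
Title: Prediction of 3D Chromatin Contact Maps from Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts 10kb-resolution, Z-score-normalized chromatin contact
    maps from single-cell ATAC-seq alone. Builds pseudobulk accessibility and
    CTCF motif tracks at 50bp, metacell Jaccard co-accessibility at 500bp, and
    feeds them through a lightweight two-feature-extractor convolutional
    network that predicts one-sided V-stripes of the contact map, assembled
    chromosome-wide by averaging overlapping predictions. Includes two-stage
    training with data augmentation, bulk Hi-C deconvolution by fine-tuning
    and per-cluster inference, distance-stratified evaluation metrics, and a
    synthetic paired scATAC/Hi-C generator with planted loops for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
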