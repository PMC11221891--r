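Package: spotgat
Title: Spot-Level Gene Expression from Histology Images via Graph Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage framework for estimating spot-level gene expression
    from tissue images. A spot embedding generator (a small convolutional
    network followed by a dual-coefficient multi-head graph-attention layer
    over the spatial neighbor graph) is trained on spatial-transcriptomics
    samples to map spot images to expression profiles. The trained encoder is
    transferred to whole-slide images paired with bulk RNA-seq gene
    expression: a gene expression predictor fuses frozen spot embeddings with
    a learned bulk embedding and is trained so that the spot-average
    reconstructs the bulk profile, yielding per-spot expression where only
    bulk data exist. A spot label predictor classifies spots as tumor or
    non-tumor (with Youden-index thresholding) so downstream summaries can be
    restricted to tumor spots. Includes patch extraction from
    coordinate-anchored spots and from coordinate-free whole-slide images,
    spatial adjacency construction, evaluation metrics, and a seeded
    synthetic-tissue generator so every stage is trainable and testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
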