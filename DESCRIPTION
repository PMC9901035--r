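Package: masir
Title: Marker-Assisted Standardization and Integration of Single-Cell
    Transcriptomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-free reference-based cell-type annotation and batch
    integration for single-cell RNA-seq. Ensemble-ranked, weighted marker
    genes identified from a labelled reference convert a log-normalized
    expression matrix into a low-dimensional cell-type score matrix, which
    replaces a learned latent space for annotation and integration.
    Includes robust rank aggregation and Lancaster p-value combination for
    marker discovery, a TF-IDF marker scoring transform, consensus
    over-clustering annotation with a certainty score for cell types
    absent from the reference, a negative-binomial multi-batch simulator,
    and annotation/integration quality metrics (accuracy, macro F1,
    silhouette, batch entropy mixing, ARI, NMI).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    igraph,
    cluster,
    uwot,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
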