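Package: criskit
Title: Discovery and Single-Sample Classification of Cancer-Cell
    Intrinsic Transcriptional Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for discovering cancer-cell intrinsic transcriptional
    subtypes from stroma-depleted expression data and classifying new
    samples. Implements consensus non-negative matrix factorization with
    cophenetic model selection, silhouette-based core-sample filtering,
    permutation-FDR multiclass differential expression, nearest shrunken
    centroid gene selection with stromal-contribution filtering,
    nearest-template prediction with resampling-based per-sample FDR, a
    rank-based multiclass top-scoring-pairs (k-TSP) single-sample
    classifier built on integrative-correlation gene filtering, sample
    set enrichment analysis, signature and receptor-activity scores, and
    per-sample mutational and copy-number load. Includes a synthetic-data
    generator emulating latent subtypes, stromal contamination and
    multi-platform distortion, so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
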