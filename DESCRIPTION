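Package: spectromics
Title: Spatially Resolved Raman Spectromics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-cell-genomics-style analysis of spatially resolved Raman
    microspectroscopy scans. Provides spectral quality control (outlier pixels,
    paraffin band removal, despiking, asymmetric-least-squares baseline),
    spatially-unaware clustering (standardized PCA with permutation-based
    component selection, shared-nearest-neighbor graph communities, tSNE/UMAP
    embeddings, per-cluster differential Raman peaks, non-negative matrix
    factorization component maps), spatially-aware clustering via a Bayesian
    mixture with t-distributed errors and a Potts Markov-random-field prior on
    the pixel lattice, pseudotime principal trees and straight-line spatial
    trajectories with loess dynamics statistics, Raman-MALDI multimodal fusion
    (landmark similarity-transform registration, imzML input, weighted
    nearest-neighbor integration, paired volcano statistics), reference-spectrum
    cell typing against immunofluorescence label masks, and clustering
    comparison metrics (IoU matrices, adjusted Rand index). A synthetic
    hyperspectral scene generator makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    Rtsne,
    uwot,
    xml2,
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
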