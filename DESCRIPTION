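Package: specvote
Title: Specimen-Level Taxon Classification from Multi-View Silhouette Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based identification of bulk-sampled invertebrate
    specimens photographed as sinking silhouettes from two orthogonal camera
    views. Provides a synthetic silhouette-sequence generator with realistic
    per-taxon frame-count and body-size structure, blob detection and geometric
    shape features with body-size estimation in square millimetres,
    leakage-free specimen-grouped dataset splitting (fixed test sets, balanced
    nested subsamples, stratified k-fold cross-validation), image augmentation
    (rotation, flips, shear), a regularized multinomial image scorer trained
    with validation-based early stopping, specimen-level aggregation by
    majority vote or score-sum voting, per-taxon precision/recall evaluation,
    and learning-curve experiments over training-set size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
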