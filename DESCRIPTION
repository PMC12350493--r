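Package: segvol
Title: Encoder-Decoder Segmentation and Volumetry for Brain MRI Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative volumetry of small brain
    structures (hypothalamus) and intracranial volume (ICV) from stacks of
    preprocessed 2D grayscale PNG slices. Provides cohort-level z-score
    intensity normalization, subject-level K-fold training of a configurable
    U-Net-style encoder-decoder with a combined cross-entropy plus soft-Jaccard
    loss, validation-IoU-weighted ensemble inference, segmentation evaluation
    (Dice, 95th-percentile Hausdorff distance in mm, volume similarity),
    positive-voxel volumetry with ICV normalization, sex-stratified
    2-SD outlier quality control, manual-correction ingestion, and unpaired
    t-test group comparison. A built-in ellipsoidal head-phantom generator
    with analytically known ground truth makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
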