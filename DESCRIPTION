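Package: wmhresample
Title: Sample-Size Resampling Experiments for Trainable White Matter
    Hyperintensity Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the size of the training sample affects
    trainable voxel-wise white matter hyperintensity (WMH) segmentation in
    populations with low lesion loads. Provides a seeded 3D phantom
    generator producing co-registered FLAIR-like and T1-like volumes with
    ground-truth lesion masks calibrated to a zero-inflated, right-skewed
    volume distribution; a leakage-aware resampling design (draws without
    replacement at several training sizes, with paired baseline/follow-up
    scans and a fixed external validation set); a voxel-wise k-nearest
    neighbour probabilistic lesion classifier over intensity and spatial
    features; and an evaluation harness computing lesion volumes, signed
    volume errors, Dice similarity, global threshold selection,
    training-set composition and volume-stratified error analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
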