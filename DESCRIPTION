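Package: octaseg
Title: Iterative Deep Segmentation of Retinal Vessel Centerlines in OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable convolutional networks for delineating retinal vessel
    centerlines in maximum-intensity projections of OCT angiography volumes.
    Implements a residual U-Net base network and two iterative refinement
    schemes (a stacked-hourglass cascade and a weight-shared recurrent U-Net),
    a class-balanced cross-entropy loss combined with a feature-space
    perceptual loss that penalises topological errors, the training protocol
    (online augmentation, inverse-time learning-rate decay, Quality-based
    early stopping, stratified fold splitting), tolerance-based delineation
    metrics (Completeness, Correctness, Quality and the precision-recall
    break-even point), per-slice 3D inference, and a synthetic OCT-A phantom
    generator so that the whole pipeline can be exercised without clinical
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
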