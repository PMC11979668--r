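Package: stagedseg
Title: Two-Stage Prior-Mask-Guided 3D Segmentation of Longitudinal Tumour MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for coarse-to-fine 3D tumour segmentation
    on longitudinal head-and-neck MRI. Implements mask-guided training-patch
    sampling, prior-image and prior-mask channel stacking, a lightweight 3D
    residual encoder-decoder network with deep supervision trained by
    SGD with Nesterov momentum, Gaussian-weighted sliding-window inference
    with optional restriction to a prior region of interest, and an
    evaluation protocol based on per-patient and aggregated (pooled) Dice
    with paired Wilcoxon signed-rank comparisons. Ships a synthetic
    longitudinal phantom generator so every stage of the pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
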