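Package: embryonet
Title: Two-Step Segmentation and Multi-Timepoint Classification of
    Cleavage-Stage Embryo Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting pregnancy outcome from time-lapse light
    microscopy of cleavage-stage human embryos. Implements a two-step
    pipeline: a U-Net segmenter that separates the embryo from the culture
    background, followed by a three-branch convolutional classifier that
    fuses per-frame features extracted at three fixed hours
    post-insemination (19, 44 and 68 hpi) into a single pregnancy
    probability, alongside a single-image baseline. Includes leakage-safe
    patient-grouped stratified splitting, the geometric-plus-noise
    augmentation recipe with x30 expansion, confusion-matrix metrics,
    embryologist-panel majority voting, and a synthetic embryo-image
    generator with controllable class signal so the whole pipeline is
    testable without clinical data. The neural-network core is a compact
    CPU reverse-mode autograd engine with Rcpp convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
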