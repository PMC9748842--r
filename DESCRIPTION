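Package: hpreg
Title: Homologous-Point Registration of Histology and MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A cross-modality 2-D image registration pipeline for
    radiology-pathology alignment. Landmarks are selected on the moving
    (histology) image with a difference-of-Gaussians scale-space detector,
    a locality-preserving transformer network predicts the homologous
    points on the fixed (MR) image via dot-product patch similarity and a
    soft-argmax over patch centers, and a thin-plate-spline resolver fits
    the paired points and warps the moving image into fixed-image space.
    Includes the training harness (masked mean-absolute-error loss,
    thin-plate-spline and rotation augmentation, mono-/multi-modal branch
    switching), registration metrics (control point deviation, Dice), and
    a synthetic phantom generator with known ground-truth correspondences
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
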