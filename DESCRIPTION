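Package: mpkbseg
Title: Knowledge-Based Multi-Planar Segmentation and Prostate Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a knowledge-based (KB) multi-planar 2D
    segmentation network for prostate whole-gland delineation and prostate
    volume (PV) estimation from T2-weighted-like MRI volumes. Three
    weight-shared plane encoders (axial, sagittal, coronal) feed a shared
    latent bottleneck; only the axial encoder is connected to the decoder via
    skip connections, and training supervision uses axial masks only. A
    cosine-distance contrastive term aligns sagittal and coronal latent
    representations to the axial branch, so that deployment degrades
    gracefully to axial-only (abbreviated) protocols. Includes NIfTI input
    and output, intensity normalization and spline resampling to a common
    reference space, a synthetic multi-planar phantom generator with analytic
    ground-truth volumes, five-fold cross-validation with ensemble-averaged
    inference, and a full volumetry and agreement stack: mask and
    ellipsoid-formula volumes (PI-RADS 2.1), Dice, average surface distance,
    relative volume difference, intraclass correlation with interpretation
    bands, Bland-Altman limits of agreement, and paired tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse,
    jsonlite
Config/testthat/edition: 3
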