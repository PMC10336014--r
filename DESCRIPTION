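Package: mri4d
Title: Navigator-Conditioned 4D Liver MRI Reconstruction with Transfer
    Learning and Ensembling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs time-resolved volumetric (4D) liver MRI from a
    single real-time 2D navigator slice by conditional slice prediction.
    A three-channel convolutional encoder-decoder (U-Net) maps a
    navigator frame plus two slices of a static reference volume to the
    moving slice at any target position; inferring all positions at one
    time point yields a 3D volume per navigator.  The package provides a
    synthetic breathing-liver phantom with known ground-truth motion, a
    compact seeded 2-D conv-net engine, transfer learning by
    fine-tuning, deep-ensemble averaging with coefficient-of-variation
    uncertainty maps, the RMSE / MDISP / DN_RMSE evaluation stack built
    on a 2-D B-spline deformable registration, and a seeded experiment
    harness (domain shift, transfer-learning versus direct training,
    ensemble size) with the accompanying statistical tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
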