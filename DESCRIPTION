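Package: cbctmoco
Title: Gate-Less Model-Based Motion Estimation and Correction for Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint reconstruction of time-resolved non-rigid motion and
    motion-compensated images from cone-beam CT projection data, without
    respiratory gating. Motion is estimated per gantry angle directly in
    projection space using a low-rank cubic B-spline spatio-temporal
    deformation model with spatial Jacobian regularization, alternated with
    motion-compensated SIRT reconstruction built on adjoint pull/push
    warping. Includes a deformable digital thorax phantom and a noisy
    dynamic acquisition simulator for validation, plus SSIM, edge-spread
    width and motion RMSE evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    splines,
    stats,
    minpack.lm,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
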