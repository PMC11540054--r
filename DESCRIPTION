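Package: cbctdir
Title: Deformable CT-to-CBCT Registration and Evaluation for Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable image registration between planning CT and kilovoltage
    cone-beam CT for image-guided adaptive radiotherapy of the pelvis.
    Implements an iterative optical-flow (demons-type) registration, a
    multiresolution cubic B-spline registration driven by the sum of squared
    differences, a hybrid scheme that seeds the optical flow with the B-spline
    displacement field, and a two-step scheme in which organ intensities are
    overridden before registration and the resulting field is applied to the
    original planning CT. Includes the supporting preprocessing (treatment-table
    removal, gas-pocket detection and filling, structure intensity override),
    TG-132-style contour agreement metrics (Dice, 95% Hausdorff distance),
    image-quality indices (SNR, CNR, uniformity, identity-function profile,
    MAE, ME, PSNR, SSIM), dose-volume histogram metrics and gamma-index dose
    comparison, and deterministic digital phantoms (an electron-density disc
    phantom and a deformable pelvis with ground-truth displacement fields) that
    supply all test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
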