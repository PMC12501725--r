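Package: t1rhomap
Title: Accelerated T1rho Mapping of Knee Cartilage from Reduced Acquisitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise quantification of the spin-lattice relaxation time in the
    rotating frame (T1rho) of knee cartilage from magnitude MR volumes. Provides
    the mono-exponential signal model with closed-form two-point and
    Levenberg-Marquardt multi-point nonlinear least-squares fitting, a synthetic
    knee phantom generator (multi spin-lock-time volumes with Rician noise, a
    proton-density-weighted surrogate contrast, out-of-model bone-marrow regions
    and a labeled cartilage mask), two learning-based predictors (a 2D U-Net
    regressor with an output-range limiter and a 1D multi-layer perceptron over
    voxel intensity pairs) trained with L1 loss under stratified k-fold
    cross-validation, sliding-window and voxelwise whole-volume inference, and
    the evaluation statistics used for compositional MRI (MAE, MAPE, regional
    error, regional percentage error, bias, and SSIM within a region of
    interest). Volumes are read and written as NIfTI-1 with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
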