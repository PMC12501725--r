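# t1rhomap

Accelerated T1rho quantification of knee cartilage from reduced MR
acquisitions, in R.

T1rho (spin-lattice relaxation in the rotating frame) is a compositional MRI
marker: cartilage T1rho rises with the proteoglycan loss of early
osteoarthritis. Conventional mapping acquires several T1rho-weighted volumes
at increasing spin-lock times (TSL) and fits the mono-exponential model
`I_k = I0 * exp(-TSL_k / T1rho)` per voxel — robust, but slow to acquire.
This package implements and evaluates the accelerated alternative: predict
the voxelwise T1rho map from just **two** volumes — one baseline-like
contrast (the TSL = 0 volume, or a proton-density-weighted anatomical volume
for which no signal model exists) plus a single T1rho-weighted volume at one
non-zero TSL — using learned regressors supervised by conventional 4-point
NLLS fits.

For researchers in quantitative MRI / musculoskeletal imaging who want to
prototype and stress-test reduced-acquisition T1rho pipelines without
scanner data, the package provides:

* the signal model with closed-form two-point and vectorized
  Levenberg–Marquardt multi-point NLLS fitting (`signal_intensity`,
  `two_point_fit`, `nlls_fit`, `fit_volume`);
* a deterministic synthetic knee phantom: multi-TSL volumes with Rician
  noise, a PD-weighted surrogate contrast, an out-of-model bone-marrow
  region, and a labeled cartilage mask (femoral / lateral tibial / medial
  tibial / patellar) with ground-truth T1rho fields (`phantom_spec`,
  `generate_cohort`);
* two predictors with their published training recipes: a 2D U-Net patch
  regressor with an output-range limiter `min(ReLU(x) + 10, 100)` ms, and a
  per-voxel MLP over intensity pairs (`build_unet`, `build_mlp`,
  `train_unet`, `train_mlp`) — backed by a small deterministic compiled
  layer engine, no external deep-learning framework required;
* stratified k-fold cross-validation with per-subject prediction by unseen
  models (`make_folds`, `run_cross_validation`), sliding-window and
  voxelwise whole-volume inference (`sliding_window_map`, `voxelwise_map`);
* the evaluation statistics of compositional MRI: MAE, MAPE, regional error
  (RE), regional percentage error (RPE), signed bias, and SSIM within an ROI
  (`compute_subject_metrics`, `summarize_cohort`, `ssim_roi`);
* NIfTI-1 + JSON-sidecar I/O, YAML run configs, and a CLI
  (`inst/cli/t1rho.R`) covering simulate / fit / crossval / predict /
  evaluate.

## Worked example

Simulate a 12-knee cohort, derive the 4-point NLLS ground truth, and
cross-validate the MLP on the two-volume (TSL 0, TSL 50 ms) acquisition:

```r
library(t1rhomap)

proto  <- t1rho_protocol(c(0, 10, 30, 50))          # TSLs in ms, FSL 300 Hz
cohort <- generate_cohort(12, phantom_spec(snr = 30, seed = 1), proto, seed = 1)
truth  <- lapply(cohort, function(s) fit_volume(s$volumes, proto, method = "nlls"))
names(truth) <- vapply(cohort, function(s) s$id, "")

folds <- make_folds(vapply(cohort, function(s) s$id, ""),
                    vapply(cohort, function(s) s$stratum, ""), k = 3, seed = 1)
prof  <- fast_profile(seed = 1)
res   <- run_cross_validation(cohort, folds, model = "mlp",
                              combo = list(i0 = "tsl0", ik = 50),
                              train_cfg = prof$mlp_train,
                              net_cfg = prof$mlp_cfg, truth_maps = truth)
res$summary
#>     metric        mean        sd
#> 1      mae  2.16140886 0.0802437
#> 2     mape  4.10686223 0.1999527
#> 3       re  0.27791863 0.1840721
#> 4      rpe  0.53357265 0.3734358
#> 5     bias -0.02982775 0.3423046
#> 6 pct_bias -0.02306735 0.6704143
```

Reading: across the 12 held-out predictions the voxelwise error is ~2.2 ms
(MAE) / ~4.1 % (MAPE), while the *regional* error — the scale on which
cartilage composition is actually read — is ~0.5 % (RPE), far inside the
5 % performance target, with a cohort bias near zero. The U-Net variant
(`model = "unet"`, `combo = list(i0 = "pd", ik = 50)`) covers the
PD-weighted reduced acquisition, for which NLLS fitting is not applicable
at all.

The methods vignette (`vignettes/t1rho-mapping.Rmd`) documents the signal
model, the phantom's design and its limits, both architectures and training
recipes, and every numerical choice.

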