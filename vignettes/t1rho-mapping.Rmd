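---
title: "Accelerated T1rho mapping of knee cartilage: models, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated T1rho mapping of knee cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1rhomap)
```

## The quantification problem

Spin-lattice relaxation in the rotating frame (T1rho) is a compositional MRI
marker of cartilage: proteoglycan loss in early osteoarthritis raises the
cartilage T1rho value. Conventional quantification acquires several
T1rho-weighted volumes at increasing spin-lock times (TSL) and fits the
mono-exponential signal model per voxel,

$$ I_k = I_0 \, e^{-\mathrm{TSL}_k / T_{1\rho}}, $$

which costs several minutes of scan time. This package implements an
accelerated alternative: predict the voxelwise T1rho map from a *reduced*
acquisition — one baseline-like volume (either the TSL = 0 contrast or a
proton-density-weighted anatomical volume, which has comparable contrast but
no exact signal-model link to T1rho) plus a single T1rho-weighted volume at
one non-zero TSL — using a learned regressor supervised by conventional
multi-point fits. Two architectures are provided: a 2D U-Net over image
patches and a per-voxel multi-layer perceptron (MLP) over intensity pairs.
Both act as function approximators of the (inverse) signal equation; the
U-Net additionally sees spatial context, which matters when the inputs
contain noise and tissue that does not follow the decay model at all (bone
marrow, and the PD-weighted contrast as a whole).

## Fitting machinery

`signal_intensity()`, `two_point_fit()` and `nlls_fit()` implement the decay
model and its inversion. The multi-point fit is a Levenberg–Marquardt
minimization over $(I_0, T_{1\rho})$, initialized from the log-linear
regression of $\log I$ on TSL and constrained to $T_{1\rho} \in [1, 500]$ ms
and $I_0 \in [0, 10 \max I]$; optima on a bound are flagged `clamped`.
Convergence uses a relative parameter-step tolerance of `1e-8` with at most
200 iterations. Voxels with any non-positive sample are marked invalid
rather than fitted (magnitude data with Rician noise is almost surely
positive, so this only affects empty background in noise-free renders). The
fitter is vectorized over voxels — all voxels of a volume are iterated
simultaneously with per-voxel damping — so a whole-volume 4-point fit takes
seconds. With two samples it reproduces the closed form
$T_{1\rho} = \Delta\mathrm{TSL} / \log(I_0/I_k)$ exactly; the test suite
also checks it voxel-by-voxel against an independent dense grid search and
against `minpack.lm`.

## The synthetic phantom

No public dataset accompanies this problem, so the package ships a
first-class generator (`phantom_spec()`, `make_t1rho_field()`,
`generate_cohort()`) that emulates the acquisition at desk scale. Choices,
once, with rationale:

* **Geometry.** Default grid 8 × 128 × 128 with cartilage on the 6 central
  slices: a femoral annular arc (2–4 voxels thick), tibial plateau bands
  split lateral/medial across the slice stack, and a short curved patellar
  band — thin curved structures like real cartilage, at a size where a full
  study runs in minutes on one core.
* **T1rho values.** Region bases 50 / 45 / 45 / 55 ms (femoral, lateral
  tibial, medial tibial, patellar) plus a smooth ±10 ms low-frequency
  perturbation, clipped to [25, 80] ms; conforming background tissue at
  30 ms. This brackets typical in-vivo cartilage values, whose cohort mean
  is around 45 ms.
* **Out-of-model region.** A contiguous "bone marrow" core inside the
  femoral condyle follows $I(\mathrm{TSL}) = c\,(0.8 + 0.2\,
  e^{-\mathrm{TSL}/150})$ — a bright, slow, offset decay the two-parameter
  model cannot represent. It exists so that the unmasked-input question
  (does non-conforming context help or hurt?) is testable.
* **Noise.** Rician: $\sqrt{(I+n_1)^2 + n_2^2}$ with
  $\sigma = \bar I_{0,\mathrm{ROI}} / \mathrm{SNR}$, because inputs are
  magnitude images; the default SNR is 30. Means of noisy magnitudes are
  positively biased at low SNR, as in real data.
* **Texture.** The baseline intensity field carries a static fine-scale
  texture (smoothed white noise, 10 % amplitude) shared by all contrasts.
  Real tissue has anatomical texture; without it, windowed structural
  similarity between contrasts is dominated by the noise floor and the
  phantom would understate how well-aligned real registered pairs look.
* **PD surrogate.** $\mathrm{pd} = g \cdot \bar I \,(I_{\mathrm{TSL}=0} /
  \bar I)^{\gamma} \cdot B(x)$ with gain $g = 1.2$, contrast exponent
  $\gamma = 0.9$ applied around the mean tissue intensity $\bar I$ (so the
  arbitrary-unit scale is preserved), a smooth ±15 % multiplicative bias
  field $B$, and an independent noise draw. Similar-but-not-identical
  contrast: mono-exponential fitting through it fails while learning
  succeeds. An optional rigid in-plane shift (`misalignment_mm`) serves as a
  registration stressor. The true joint distribution of PD vs. TSL = 0
  contrast in vivo is unknowable from first principles; this family is
  parameterized so its difficulty can be varied, not claimed to match a
  scanner.
* **Cohort structure.** Subjects carry a binary stratum label (three
  "patients" per "volunteer"); patient cartilage bases are raised by 5 ms,
  emulating osteoarthritic elevation, so stratified folding has something
  real to balance.

Every generator output is a pure function of its spec and seed.

What passing tests on this phantom do **not** show: robustness to real
through-plane anatomy, B0/B1 inhomogeneity, fat signal, registration error
beyond rigid shifts, echo-train blurring, or scanner intensity
non-stationarities. The phantom makes the *pipeline* testable; it does not
certify in-vivo performance.

## Predictors

**Limiter.** Both networks end in
$\hat y = \min(\mathrm{ReLU}(x) + y_{\min},\, y_{\max})$ with defaults 10
and 100 ms, so predictions always lie in a physiologic range and gradients
of grossly mispredicted voxels are suppressed. The regressor bias is
initialized mid-range ($(y_{\min}+y_{\max})/2$); a zero initialization would
start on the flat side of the ReLU where every gradient is zero and
training could never leave the initial state.

**2D U-Net** (`unet_config()`, `build_unet()`): double 3 × 3 conv +
batch-norm + ReLU blocks per level, 2 × 2 max pooling, bilinear upsampling
with skip concatenation, 1 × 1 regressor head, limiter. Package defaults are
depth 4 with 32 base channels — a standard U-Net; the desk-scale profile
(below) trains a depth-2, 4-channel variant. Inputs are 64 × 64 patches
cropped with probability 0.8 around ROI voxels; augmentation applies random
flips (exact index reversals), rotations up to ±15°, translations up to
±8 px (one bilinear resampling applied identically to inputs and target;
masks nearest-neighbor), and Gaussian noise on the inputs only (σ = 2 % of
the normalized intensity scale). Training uses L1 loss, Adam, initial
learning rate $10^{-3}$ decayed by 0.9 per epoch, weight decay
$3\times10^{-4}$.

**1D MLP** (`mlp_config()`, `build_mlp()`): 4 FC-ReLU-BN blocks of width
64 with residual connections between equal-width blocks, a final linear
unit and (by default) the same limiter — the exact published layer sizes
are not recoverable, so these are declared package defaults. It trains on
ROI voxels only, in batches of 512 rows, with RMSProp under the same
learning-rate schedule and weight decay.

**Normalization.** Both input channels are divided by the subject-level
mean intensity of the I0-like volume inside the ROI bounding box: scanner
units are arbitrary, and a subject-level (not slice-level) scale keeps the
$I_0/I_k$ ratio — the quantity the signal model actually constrains —
meaningful.

**Loss masking.** When `roi_loss_only` is set, the L1 loss is computed over
ROI voxels only; target voxels outside the supervised set are zeroed before
augmentation so that interpolation at ROI edges cannot leak unsupervised
target content into the loss (this makes "non-ROI targets do not affect
training" an exact invariant, which the tests assert by scrambling them).
In the unmasked variant the loss runs over all voxels with a valid
ground-truth fit, including non-conforming tissue — deliberately so, since
that is the scenario the unmasked experiment probes.

## Inference and evaluation

U-Net maps are produced by a sliding 64 × 64 window over every
ROI-containing slice, stride 32, with overlapping predictions averaged
(overlap averaging suppresses edge artifacts; whether the original method
averaged or tiled is not stated, so averaging is the package's choice).
Slices smaller than the window are reflect-padded and cropped back. MLP
maps are reassembled voxel-for-voxel. Non-ROI voxels are 0 with
`valid = FALSE`; evaluation happens inside the ROI only.

Per subject, over the unified cartilage ROI (or any labeled subregion):
MAE and MAPE (voxelwise), RE $= |\overline{y} - \overline{\hat y}|$ and
RPE (regional — the clinically relevant scale, since compositional reads
use regional averages), and the signed Bias with %Bias. As printed, the
regional-error formulas carry no absolute-value bars; they are implemented
as absolute values with the signed quantity carried separately by Bias,
which matches how the quantities are tabulated (nonnegative RE/RPE next to
signed Bias). %Bias uses the subject-level mean ground truth by default,
consistent with RPE; a fixed cohort-level denominator is available as an
option. Cohort summaries are means ± sample SD (n − 1; a single subject
reports SD 0 by convention), with the cohort bias the mean of signed
per-subject biases. `ssim_roi()` computes slice-wise SSIM (Gaussian window,
σ 1.5, 11 × 11 support, data range = joint max − min) averaged over ROI
voxels, the alignment check used for registered contrast pairs.

Cross-validation (`make_folds()`, `run_cross_validation()`): subjects are
shuffled within strata and dealt round-robin, giving mutually exclusive,
jointly exhaustive folds balanced within one subject per stratum; each
subject is predicted exactly once, by the model whose training folds
exclude it. The multi-factor (sex × severity) balancing of a real study is
reduced to this single joint stratum label.

## Numerical engine

No deep-learning framework exists for R in this environment, so the layer
engine is part of the package: activations are dense matrices of stacked
slice pixels; the 3 × 3 convolutions run as vectorized single-precision
stencil kernels in compiled code (double-precision accumulators for weight
gradients), batch normalization likewise; bilinear upsampling is a cached
sparse operator, so its backward pass is exactly the transpose. Everything
is driven by R's RNG and sequential BLAS: fixed seeds give bit-identical
training runs single-threaded. Backward passes are verified against
numeric gradients and a double-precision reference convolution in the test
suite. Adam and RMSProp follow the standard formulations
($\beta = 0.9/0.999$, $\alpha = 0.99$, $\epsilon = 10^{-8}$, L2 weight
decay added to gradients).

## Desk-scale study profile

`fast_profile()` fixes the problem sizes used by the shipped study script
and the end-to-end tests: a 12-subject cohort (SNR 30), 3-fold stratified
cross-validation, 200 epochs, and a depth-2 / 4-channel U-Net trained on 2
patches per ROI slice per epoch in batches of 8 (the MLP keeps its default
4 × 64 architecture and 512-row batches). These sizes were chosen so the
whole simulate → fit → cross-validate → evaluate cycle completes in minutes
on a single core while leaving the training recipes (optimizers, learning
rates, decay, weight decay, loss, patch and window sizes) exactly as
published. With the 0.9-per-epoch decay the learning rate is numerically
negligible beyond epoch ~100, so the short schedule changes little besides
wall time. The MLP's analytic-inverse check in the test suite uses a
gentler decay (0.99 over 300 epochs) because its purpose is to probe the
architecture's approximation capacity on noise-free pairs, not to replay a
training recipe.

## Worked example

```{r example, eval = FALSE}
proto  <- t1rho_protocol(c(0, 10, 30, 50))
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
```

## Known limitations

* The phantom is 2.5-D (slice-replicated geometry with smooth 3-D
  perturbations); through-plane partial-volume effects are absent.
* Rician noise is applied per volume with a shared reference intensity; no
  coil-dependent spatial noise correlation is modelled.
* The exact published network sizes, NLLS variant and augmentation
  magnitudes are not recoverable from text; the package states its own
  defaults in the corresponding help pages.
* No Rician-bias-corrected maximum-likelihood fitting and no B0/B1
  correction are implemented; magnitude data are assumed throughout.
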