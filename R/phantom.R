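#' Labeled cartilage ROI mask
#'
#' Integer label grid: 0 = background, 1 = femoral, 2 = lateral tibial,
#' 3 = medial tibial, 4 = patellar cartilage.
#'
#' @param labels 3D integer array with values in 0..4.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (!all(labels %in% 0:4)) stop("ROI labels must be in {0,1,2,3,4}")
  structure(list(labels = array(as.integer(labels), dim(labels))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:4))
  cat("roi_mask:", paste(dim(x$labels), collapse = " x "), "voxels\n")
  cat("  femoral:", tab["1"], " lat tibial:", tab["2"],
      " med tibial:", tab["3"], " patellar:", tab["4"], "\n")
  invisible(x)
}

# Accept either a roi_mask or a bare array wherever a mask is expected.
roi_labels <- function(roi) {
  if (inherits(roi, "roi_mask")) roi$labels else {
    stopifnot(is.array(roi))
    roi
  }
}

# Deterministic seed mixing for per-subject / per-volume noise streams.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1009) %% 2147483629)
}

#' Specification of the synthetic knee phantom
#'
#' Defines the desk-scale study conditions emulated by the generator: grid
#' geometry, cartilage T1rho distribution, the out-of-model ("bone marrow")
#' region, Rician noise level and the PD-weighted surrogate contrast.
#'
#' @param grid_shape Integer triplet (slices, rows, cols).
#' @param n_slices_with_cartilage Number of central slices carrying cartilage.
#' @param t1rho_range_roi Clipping range (ms) for cartilage T1rho values.
#' @param t1rho_background T1rho (ms) of model-conforming non-cartilage tissue.
#' @param ood_fraction Approximate fraction of in-plane voxels rendered with
#'   the non-mono-exponential bone-marrow law.
#' @param snr Signal-to-noise ratio of the Rician noise (Inf = noise free),
#'   referenced to the mean baseline intensity inside the cartilage ROI.
#' @param pd_gain,pd_gamma Gain and contrast exponent of the PD surrogate.
#' @param pd_bias_amplitude Amplitude of the smooth multiplicative bias field
#'   applied to the PD surrogate (fraction of unity).
#' @param misalignment_mm In-plane rigid shift of the PD surrogate, for
#'   registration stress tests.
#' @param t1rho_shift Additive shift (ms) on all cartilage base values; used by
#'   the cohort generator to emulate osteoarthritic T1rho elevation.
#' @param seed Integer seed making every derived artifact deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(8, 128, 128),
                         n_slices_with_cartilage = 6,
                         t1rho_range_roi = c(25, 80),
                         t1rho_background = 30,
                         ood_fraction = 0.1,
                         snr = 30,
                         pd_gain = 1.2,
                         pd_gamma = 0.9,
                         pd_bias_amplitude = 0.15,
                         misalignment_mm = 0,
                         t1rho_shift = 0,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (n_slices_with_cartilage > grid_shape[1])
    stop("more cartilage slices than grid slices")
  stopifnot(length(t1rho_range_roi) == 2,
            t1rho_range_roi[1] > 0, t1rho_range_roi[2] <= 500,
            t1rho_range_roi[1] < t1rho_range_roi[2])
  stopifnot(snr > 0, ood_fraction >= 0, ood_fraction <= 1,
            pd_gain > 0, pd_gamma > 0, pd_bias_amplitude >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_slices_with_cartilage = as.integer(n_slices_with_cartilage),
                 t1rho_range_roi = as.numeric(t1rho_range_roi),
                 t1rho_background = as.numeric(t1rho_background),
                 ood_fraction = ood_fraction, snr = snr,
                 pd_gain = pd_gain, pd_gamma = pd_gamma,
                 pd_bias_amplitude = pd_bias_amplitude,
                 misalignment_mm = misalignment_mm,
                 t1rho_shift = t1rho_shift,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth low-frequency random field in [-1, 1], drawn from the current RNG
# stream: a mixture of three low-frequency 3D sinusoids.
.smooth_field <- function(dims) {
  S <- dims[1]; H <- dims[2]; W <- dims[3]
  f <- array(0, dims)
  s_idx <- (seq_len(S) - 1) / max(S - 1, 1)
  r_idx <- (seq_len(H) - 1) / max(H - 1, 1)
  c_idx <- (seq_len(W) - 1) / max(W - 1, 1)
  for (j in 1:3) {
    fr <- stats::runif(1, 0.5, 1.5); fc <- stats::runif(1, 0.5, 1.5)
    fs <- stats::runif(1, 0.25, 0.75); ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    phase <- outer(s_idx * fs, outer(r_idx * fr, c_idx * fc, "+"), "+")
    f <- f + amp * sin(2 * pi * phase + ph)
  }
  f / max(abs(f))
}

# In-plane geometry of one knee-like sagittal slice, scaled to (H, W).
# Returns integer label matrix plus logical masks for tissue / bone marrow /
# air. lateral: whether this slice belongs to the lateral half of the knee
# (controls the tibial subregion label).
.slice_geometry <- function(H, W, ood_fraction, lateral) {
  sy <- H / 128; sx <- W / 128
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  # body ellipse (everything else is air)
  body <- ((r - 64 * sy) / (60 * sy))^2 + ((c - 66 * sx) / (58 * sx))^2 <= 1
  # femoral condyle and its bone-marrow core (out-of-model region)
  cy <- 48 * sy; cx <- 70 * sx
  rad <- sqrt((r - cy)^2 + ((c - cx) * sy / sx)^2)      # isotropized radius
  r_ood <- min(sqrt(ood_fraction * H * W / pi), 24 * sy)
  ood <- body & rad <= r_ood
  lab <- matrix(0L, H, W)
  # femoral cartilage: inferior annulus arc around the condyle
  ang <- atan2(r - cy, (c - cx) * sy / sx) * 180 / pi    # rows grow downward
  fem <- rad >= 28 * sy & rad <= 30.5 * sy & ang >= 20 & ang <= 160
  lab[fem & body] <- 1L
  # tibial cartilage: thin band on the tibial plateau
  tib <- r >= 83 * sy & r <= 85 * sy & c >= (cx - 30 * sx) & c <= (cx + 30 * sx)
  lab[tib & body & lab == 0L] <- if (lateral) 2L else 3L
  # patellar cartilage: short curved anterior band
  pat <- abs(c - (20 * sx + 0.06 * (r - 48 * sy)^2 * sx / sy)) <= 1.5 * sx &
    r >= 38 * sy & r <= 58 * sy
  lab[pat & body & lab == 0L] <- 4L
  lab[ood] <- 0L
  list(labels = lab, body = body, ood = ood)
}

#' Ground-truth T1rho field and cartilage mask of a phantom subject
#'
#' Draws thin curved cartilage bands (femoral annular arc, tibial plateau
#' bands split lateral/medial across slices, an anterior patellar band) on the
#' central slices and assigns each region a base T1rho plus a smooth
#' low-frequency perturbation, clipped to `t1rho_range_roi`. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `t1rho` (3D array, ms; 0 outside the ROI) and `roi`
#'   (a [roi_mask()]). The full scene (baseline intensities, tissue/air/
#'   bone-marrow masks) is attached as attribute `"scene"` for the renderer.
#' @export
make_t1rho_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$grid_shape[1]; H <- spec$grid_shape[2]; W <- spec$grid_shape[3]
  if (H < 48 || W < 48)
    stop("grid too small to place the four cartilage subregions (need >= 48x48)")
  set.seed(spec$seed)
  first <- (S - spec$n_slices_with_cartilage) %/% 2 + 1
  cart_slices <- seq(first, length.out = spec$n_slices_with_cartilage)
  labels <- array(0L, spec$grid_shape)
  body <- array(FALSE, spec$grid_shape)
  ood <- array(FALSE, spec$grid_shape)
  half <- cart_slices[ceiling(length(cart_slices) / 2)]
  for (s in seq_len(S)) {
    g <- .slice_geometry(H, W, spec$ood_fraction, lateral = s <= half)
    body[s, , ] <- g$body
    ood[s, , ] <- g$ood
    if (s %in% cart_slices) labels[s, , ] <- g$labels
  }
  bases <- c(50, 45, 45, 55) + spec$t1rho_shift
  pert <- .smooth_field(spec$grid_shape) * 10
  t1 <- array(0, spec$grid_shape)
  for (lb in 1:4) {
    m <- labels == lb
    t1[m] <- bases[lb] + pert[m]
  }
  inroi <- labels > 0
  t1[inroi] <- pmin(pmax(t1[inroi], spec$t1rho_range_roi[1]),
                    spec$t1rho_range_roi[2])
  # baseline (TSL = 0) intensity field: smooth bright tissue, brighter marrow,
  # plus a static fine-scale texture shared by all contrasts (anatomical
  # texture, not noise: it cancels in intensity ratios)
  i0 <- array(0, spec$grid_shape)
  ivar <- .smooth_field(spec$grid_shape)
  tex <- array(stats::rnorm(prod(spec$grid_shape)), spec$grid_shape)
  tex <- .box_smooth_inplane(tex)
  tex <- tex / stats::sd(tex)
  i0[body] <- 100 * (1 + 0.2 * ivar[body])
  i0[inroi] <- 115 * (1 + 0.15 * ivar[inroi])
  i0[ood] <- 160 * (1 + 0.1 * ivar[ood])
  i0 <- i0 * (1 + 0.1 * tex)
  i0[i0 < 0] <- 0
  out <- list(t1rho = t1, roi = roi_mask(labels))
  attr(out, "scene") <- list(i0 = i0, body = body, ood = ood,
                             cart_slices = cart_slices)
  out
}

# light 3x3 in-plane box smoothing (keeps texture correlated over ~2 voxels)
.box_smooth_inplane <- function(a) {
  out <- a
  H <- dim(a)[2]; W <- dim(a)[3]
  for (s in seq_len(dim(a)[1])) {
    m <- a[s, , ]
    acc <- m; cnt <- matrix(1, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      rs <- max(1, 1 + dy):min(H, H + dy)
      cs <- max(1, 1 + dx):min(W, W + dx)
      acc[rs - dy, cs - dx] <- acc[rs - dy, cs - dx] + m[rs, cs]
      cnt[rs - dy, cs - dx] <- cnt[rs - dy, cs - dx] + 1
    }
    out[s, , ] <- acc / cnt
  }
  out
}

# Out-of-model "bone marrow" law: slow, offset decay the mono-exponential
# model cannot represent.
.ood_signal <- function(c_int, tsl) c_int * (0.8 + 0.2 * exp(-tsl / 150))

#' Render the multi-TSL weighted volumes of a phantom scene
#'
#' ROI and model-conforming background tissue follow the mono-exponential
#' signal model with the scene's per-voxel baseline intensity; the contiguous
#' bone-marrow region follows a non-conforming offset-decay law; air is zero.
#' Rician noise is applied at `spec$snr` (skip with `snr = Inf`).
#'
#' @param field Output of [make_t1rho_field()] (carries the scene attribute).
#' @param roi The [roi_mask()] belonging to `field`.
#' @param protocol A [t1rho_protocol()].
#' @param spec The [phantom_spec()] used to create `field`.
#' @return List of [weighted_volume()] objects, one per protocol TSL.
#' @export
render_weighted_volumes <- function(field, roi, protocol, spec) {
  scene <- attr(field, "scene")
  if (is.null(scene)) stop("'field' must come from make_t1rho_field()")
  labels <- roi_labels(roi)
  stopifnot(identical(dim(labels), dim(field$t1rho)))
  t1 <- field$t1rho
  t1_all <- array(spec$t1rho_background, dim(t1))
  t1_all[labels > 0] <- t1[labels > 0]
  conforming <- scene$body & !scene$ood
  ref <- mean(scene$i0[labels > 0])
  lapply(seq_along(protocol$tsls), function(k) {
    tsl <- protocol$tsls[k]
    img <- array(0, dim(t1))
    img[conforming] <- scene$i0[conforming] * exp(-tsl / t1_all[conforming])
    img[scene$ood] <- .ood_signal(scene$i0[scene$ood], tsl)
    if (is.finite(spec$snr))
      img <- add_rician_noise(img, spec$snr, .derive_seed(spec$seed, 100 + k),
                              reference = ref)
    weighted_volume(img, contrast = tsl)
  })
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude-MR noise model: `out = sqrt((I + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation
#' `reference / snr`. At low SNR the output is positively biased, as in real
#' magnitude images.
#'
#' @param volume A [weighted_volume()] or a numeric array.
#' @param snr Positive signal-to-noise ratio; `Inf` returns the input.
#' @param seed Integer seed for the noise draw.
#' @param reference Reference intensity defining the noise scale; defaults to
#'   the mean positive intensity of the input. Pass the mean ROI baseline
#'   intensity to reproduce the cohort generator's convention.
#' @return Same type as `volume`.
#' @export
add_rician_noise <- function(volume, snr, seed, reference = NULL) {
  stopifnot(snr > 0)
  arr <- if (inherits(volume, "weighted_volume")) volume$data else volume
  if (!is.finite(snr)) return(volume)
  if (is.null(reference)) reference <- mean(arr[arr > 0])
  sigma <- reference / snr
  set.seed(as.integer(seed))
  n1 <- array(stats::rnorm(length(arr), 0, sigma), dim(arr))
  n2 <- array(stats::rnorm(length(arr), 0, sigma), dim(arr))
  out <- sqrt((arr + n1)^2 + n2^2)
  if (inherits(volume, "weighted_volume")) {
    volume$data <- out
    volume
  } else out
}

#' Render the PD-weighted surrogate of the TSL = 0 contrast
#'
#' The PD-weighted anatomical acquisition has contrast comparable to, but not
#' identical with, the TSL = 0 spin-lock image. The surrogate is
#' `pd = pd_gain * I^pd_gamma * B(x)` with `B` a smooth multiplicative bias
#' field of amplitude `pd_bias_amplitude`, an optional in-plane rigid shift
#' (`misalignment_mm`, for registration stress tests) and an independent
#' Rician noise draw at `spec$snr`.
#'
#' @param vol_tsl0 The (noise-free) TSL = 0 [weighted_volume()].
#' @param spec A [phantom_spec()].
#' @param seed Seed for the bias field and the noise draw; defaults to a
#'   stream derived from `spec$seed`.
#' @param reference Noise reference intensity (see [add_rician_noise()]).
#' @return A [weighted_volume()] tagged `"pd"`.
#' @export
render_pd_surrogate <- function(vol_tsl0, spec, seed = .derive_seed(spec$seed, 7),
                                reference = NULL) {
  stopifnot(inherits(vol_tsl0, "weighted_volume"))
  if (vol_tsl0$contrast != "t1rho" || vol_tsl0$tsl != 0)
    stop("'vol_tsl0' must be the TSL = 0 contrast")
  arr <- vol_tsl0$data
  # contrast exponent applied around the mean tissue intensity so the
  # arbitrary-unit scale is preserved: pd = gain * ref * (I/ref)^gamma
  ref0 <- mean(arr[arr > 0])
  out <- spec$pd_gain * ref0 * (arr / ref0)^spec$pd_gamma
  if (spec$pd_bias_amplitude > 0) {
    set.seed(as.integer(seed))
    out <- out * (1 + spec$pd_bias_amplitude * .smooth_field(dim(arr)))
  }
  if (spec$misalignment_mm != 0) {
    sh <- round(spec$misalignment_mm / vol_tsl0$voxel_spacing[2])
    if (sh != 0) {
      shifted <- array(0, dim(out))
      H <- dim(out)[2]
      src <- seq_len(H) - sh
      okr <- src >= 1 & src <= H
      shifted[, which(okr), ] <- out[, src[okr], ]
      out <- shifted
    }
  }
  if (is.finite(spec$snr)) {
    if (is.null(reference)) reference <- mean(out[out > 0])
    out <- add_rician_noise(out, spec$snr, .derive_seed(seed, 11),
                            reference = reference)
  }
  weighted_volume(out, contrast = "pd", voxel_spacing = vol_tsl0$voxel_spacing)
}

#' Generate a synthetic cohort of phantom subjects
#'
#' Each subject gets its own seed-derived geometry perturbation, T1rho field,
#' noise realization and PD surrogate. Subjects carry a binary stratum label
#' emulating the patient / healthy-volunteer composition of a clinical OA
#' cohort (roughly one volunteer per three patients); "patient" subjects have
#' their cartilage T1rho bases raised by 5 ms, emulating proteoglycan loss.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param spec Cohort-level [phantom_spec()]; per-subject specs derive their
#'   seeds from `seed`.
#' @param protocol A [t1rho_protocol()].
#' @param seed Master seed; defaults to `spec$seed`.
#' @return List of `phantom_subject` objects with elements `id`, `volumes`
#'   (noisy, one per TSL), `pd_volume`, `roi`, `truth` (a `t1rho_map` of the
#'   generating field, valid exactly on the ROI), `stratum` and `spec`.
#' @export
generate_cohort <- function(n_subjects, spec = phantom_spec(),
                            protocol = t1rho_protocol(c(0, 10, 30, 50)),
                            seed = spec$seed) {
  stopifnot(n_subjects >= 1)
  n_vol <- max(1L, round(n_subjects * 0.25))
  lapply(seq_len(n_subjects), function(s) {
    stratum <- if (s <= n_vol) "volunteer" else "patient"
    sspec <- spec
    sspec$seed <- .derive_seed(seed, s)
    sspec$t1rho_shift <- spec$t1rho_shift + if (stratum == "patient") 5 else 0
    noisefree <- sspec; noisefree$snr <- Inf
    field <- make_t1rho_field(noisefree)
    scene <- attr(field, "scene")
    clean <- render_weighted_volumes(field, field$roi, protocol, noisefree)
    ref <- mean(scene$i0[roi_labels(field$roi) > 0])
    vols <- lapply(seq_along(clean), function(k) {
      if (is.finite(spec$snr))
        add_rician_noise(clean[[k]], spec$snr,
                         .derive_seed(sspec$seed, 100 + k), reference = ref)
      else clean[[k]]
    })
    pd <- render_pd_surrogate(clean[[which(protocol$tsls == 0)[1]]], sspec,
                              reference = ref)
    truth <- t1rho_map(field$t1rho, roi_labels(field$roi) > 0)
    structure(list(id = sprintf("sub-%03d", s), volumes = vols,
                   pd_volume = pd, roi = field$roi, truth = truth,
                   stratum = stratum, spec = sspec, protocol = protocol),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("phantom_subject %s (%s): %d T1rho-weighted volumes + PD, %s grid\n",
              x$id, x$stratum, length(x$volumes),
              paste(dim(x$roi$labels), collapse = " x ")))
  invisible(x)
}
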