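#' Subject-level T1rho error metrics
#'
#' Computes the compositional-MRI evaluation statistics over the selected ROI
#' voxels of one subject: voxelwise MAE (ms) and MAPE (%), regional error
#' RE = |mean(truth) - mean(pred)| (ms) and its percentage form RPE (%), and
#' the signed Bias = mean(pred) - mean(truth) (ms) with %Bias relative to the
#' mean ground truth. Regional metrics compare means of the region, which is
#' how compositional measures such as T1rho are used clinically; RE is never
#' larger than MAE.
#'
#' @param pred,truth `t1rho_map` objects (or bare 3D arrays).
#' @param roi A [roi_mask()] or integer label array.
#' @param label `"all"` for the unified cartilage ROI or a subregion label
#'   1-4 (femoral, lateral tibial, medial tibial, patellar).
#' @param pct_bias_denominator `"subject"` (this subject's mean ground truth,
#'   consistent with RPE) or a number: a fixed cohort-level mean T1rho in ms.
#' @return A one-row `data.frame` with columns `mae`, `mape`, `re`, `rpe`,
#'   `bias`, `pct_bias`, `n_voxels`.
#' @export
compute_subject_metrics <- function(pred, truth, roi, label = "all",
                                    pct_bias_denominator = "subject") {
  pv <- if (inherits(pred, "t1rho_map")) pred$values else pred
  pok <- if (inherits(pred, "t1rho_map")) pred$valid else array(TRUE, dim(pv))
  tv <- if (inherits(truth, "t1rho_map")) truth$values else truth
  tok <- if (inherits(truth, "t1rho_map")) truth$valid else array(TRUE, dim(tv))
  lab <- roi_labels(roi)
  stopifnot(identical(dim(pv), dim(tv)), identical(dim(pv), dim(lab)))
  sel <- if (identical(label, "all")) lab > 0 else lab == as.integer(label)
  sel <- sel & pok & tok
  if (!any(sel)) stop("empty ROI selection")
  y <- tv[sel]; yh <- pv[sel]
  if (any(y <= 0)) stop("ground truth must be strictly positive on the selection")
  mae <- mean(abs(y - yh))
  mape <- mean(abs(y - yh) / y) * 100
  bias <- mean(yh) - mean(y)
  re <- abs(bias)
  rpe <- 100 * re / mean(y)
  denom <- if (identical(pct_bias_denominator, "subject")) mean(y)
           else as.numeric(pct_bias_denominator)
  data.frame(mae = mae, mape = mape, re = re, rpe = rpe, bias = bias,
             pct_bias = 100 * bias / denom, n_voxels = sum(sel))
}

#' Per-subregion metrics breakdown
#'
#' @inheritParams compute_subject_metrics
#' @return A `data.frame` with one row per region (`all` plus each nonzero
#'   label present in the mask).
#' @export
compute_region_metrics <- function(pred, truth, roi,
                                   pct_bias_denominator = "subject") {
  lab <- roi_labels(roi)
  regions <- c("all", sort(unique(lab[lab > 0])))
  out <- do.call(rbind, lapply(regions, function(r) {
    m <- compute_subject_metrics(pred, truth, roi, label = r,
                                 pct_bias_denominator = pct_bias_denominator)
    cbind(region = as.character(r), m)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort summary of per-subject metric reports
#'
#' Mean and sample standard deviation (n - 1; 0 for a single subject) of each
#' metric across subjects. The cohort bias is the mean of the signed
#' per-subject biases, so opposite-signed subject biases cancel while their
#' regional errors do not; consequently |cohort bias| <= mean RE.
#'
#' @param reports List (or row-bound `data.frame`) of per-subject reports from
#'   [compute_subject_metrics()].
#' @return A `data.frame` with one row per metric (`mean`, `sd`), plus the
#'   signed cohort bias as attribute `"cohort_bias"`.
#' @export
summarize_cohort <- function(reports) {
  if (is.data.frame(reports)) df <- reports
  else {
    if (length(reports) == 0) stop("no reports to summarize")
    df <- do.call(rbind, reports)
  }
  if (nrow(df) == 0) stop("no reports to summarize")
  metrics <- c("mae", "mape", "re", "rpe", "bias", "pct_bias")
  mu <- vapply(metrics, function(m) mean(df[[m]]), 0)
  sdv <- vapply(metrics, function(m) if (nrow(df) > 1) stats::sd(df[[m]]) else 0, 0)
  out <- data.frame(metric = metrics, mean = unname(mu), sd = unname(sdv))
  attr(out, "cohort_bias") <- unname(mu["bias"])
  out
}

# Separable "same"-size Gaussian convolution with edge renormalization:
# banded operator applied from both sides, divided by the convolved window
# mass so means near edges stay unbiased.
.gauss_band <- function(n, sigma, half) {
  taps <- stats::dnorm(-half:half, sd = sigma)
  A <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) A[cbind(idx, idx + d)] <- taps[d + half + 1]
    else A[cbind(idx - d, idx)] <- taps[d + half + 1]
  }
  A
}

.gauss_filter2 <- function(X, Ar, Ac) Ar %*% X %*% t(Ac)

#' Structural similarity restricted to an ROI
#'
#' Standard SSIM computed slice by slice with a Gaussian window (sigma 1.5,
#' 11x11 support), then averaged over the ROI voxels only. Used as the
#' inter-contrast alignment check between a registered anatomical volume and
#' the spin-lock frame.
#'
#' @param a,b 3D arrays (or `weighted_volume`s) of identical shape.
#' @param roi A [roi_mask()]; must contain at least one voxel.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param half Half-width of the window support (11x11 for the default 5).
#' @param data_range Dynamic range L; defaults to max - min over both volumes.
#' @return Mean SSIM over the ROI, in `[-1, 1]`.
#' @export
ssim_roi <- function(a, b, roi, sigma = 1.5, half = 5L, data_range = NULL) {
  A <- if (inherits(a, "weighted_volume")) a$data else a
  B <- if (inherits(b, "weighted_volume")) b$data else b
  lab <- roi_labels(roi)
  stopifnot(identical(dim(A), dim(B)), identical(dim(A), dim(lab)))
  if (!any(lab > 0)) stop("empty ROI")
  if (is.null(data_range)) data_range <- max(A, B) - min(A, B)
  if (data_range <= 0) data_range <- 1
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  H <- dim(A)[2]; W <- dim(A)[3]
  Ar <- .gauss_band(H, sigma, half); Ac <- .gauss_band(W, sigma, half)
  Nr <- .gauss_filter2(matrix(1, H, W), Ar, Ac)
  vals <- numeric(0)
  for (s in seq_len(dim(A)[1])) {
    m <- lab[s, , ] > 0
    if (!any(m)) next
    x <- A[s, , ]; y <- B[s, , ]
    mx <- .gauss_filter2(x, Ar, Ac) / Nr
    my <- .gauss_filter2(y, Ar, Ac) / Nr
    vxx <- .gauss_filter2(x * x, Ar, Ac) / Nr - mx^2
    vyy <- .gauss_filter2(y * y, Ar, Ac) / Nr - my^2
    vxy <- .gauss_filter2(x * y, Ar, Ac) / Nr - mx * my
    ss <- ((2 * mx * my + C1) * (2 * vxy + C2)) /
      ((mx^2 + my^2 + C1) * (vxx + vyy + C2))
    vals <- c(vals, ss[m])
  }
  mean(vals)
}
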