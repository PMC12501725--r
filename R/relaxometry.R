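#' Acquisition protocol for spin-lock prepared imaging
#'
#' Bundles the ordered spin-lock times (TSL, ms) and the spin-lock frequency
#' (FSL, Hz) of a multi-contrast T1rho acquisition. The FSL is carried as
#' metadata only; it does not enter the mono-exponential relaxation model.
#'
#' @param tsls Numeric vector of spin-lock times in ms, strictly increasing,
#'   all non-negative. The first entry may be 0.
#' @param fsl Spin-lock frequency in Hz (default 300, a common clinical value).
#' @return An object of class `t1rho_protocol`.
#' @examples
#' t1rho_protocol(c(0, 10, 30, 50))
#' @export
t1rho_protocol <- function(tsls, fsl = 300) {
  if (!is.numeric(tsls) || length(tsls) == 0 || any(!is.finite(tsls)))
    stop("'tsls' must be a non-empty finite numeric vector")
  tsls <- as.numeric(tsls)
  if (any(tsls < 0)) stop("spin-lock times must be >= 0")
  if (is.unsorted(tsls, strictly = TRUE)) stop("'tsls' must be strictly increasing")
  if (!is.numeric(fsl) || length(fsl) != 1 || !is.finite(fsl) || fsl <= 0)
    stop("'fsl' must be a single positive number")
  structure(list(tsls = tsls, fsl = as.numeric(fsl)), class = "t1rho_protocol")
}

#' @export
print.t1rho_protocol <- function(x, ...) {
  cat("T1rho acquisition protocol\n")
  cat("  TSL (ms):", paste(x$tsls, collapse = "/"), "\n")
  cat("  FSL (Hz):", x$fsl, "\n")
  invisible(x)
}

#' A single contrast-weighted magnitude volume
#'
#' Wraps one 3D non-negative intensity grid together with its contrast tag:
#' either the spin-lock time (ms) of a T1rho-weighted acquisition or `"pd"`
#' for a proton-density-weighted anatomical volume.
#'
#' @param data 3D numeric array of non-negative intensities (arbitrary units),
#'   indexed (slice, row, col).
#' @param contrast Either a single non-negative number (the TSL in ms) or the
#'   string `"pd"`.
#' @param voxel_spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `weighted_volume`.
#' @export
weighted_volume <- function(data, contrast, voxel_spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("'data' must be a 3D array")
  if (any(!is.finite(data))) stop("'data' must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  if (identical(contrast, "pd")) {
    tag <- "pd"; tsl <- NA_real_
  } else if (is.numeric(contrast) && length(contrast) == 1 && is.finite(contrast) &&
             contrast >= 0) {
    tag <- "t1rho"; tsl <- as.numeric(contrast)
  } else stop("'contrast' must be a TSL in ms (>= 0) or \"pd\"")
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stop("'voxel_spacing' must be three positive numbers (mm)")
  structure(list(data = data, contrast = tag, tsl = tsl,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "weighted_volume")
}

#' @export
print.weighted_volume <- function(x, ...) {
  tag <- if (x$contrast == "pd") "PD-weighted" else sprintf("T1rho-weighted (TSL %g ms)", x$tsl)
  cat(sprintf("weighted_volume: %s, %s voxels\n", tag,
              paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Default T1rho fit bounds
#'
#' Cartilage T1rho lies around 20-80 ms; the bounds are generous but finite so
#' that degenerate (non-decaying or all-noise) voxels are clamped rather than
#' diverging.
#'
#' @param lower,upper T1rho bounds in ms.
#' @return A list with elements `lower` and `upper`.
#' @export
t1rho_fit_bounds <- function(lower = 1, upper = 500) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower > 0, upper > lower)
  list(lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Mono-exponential spin-lock signal model
#'
#' Magnitude signal of a T1rho-prepared acquisition at spin-lock time `tsl`:
#' `I(tsl) = i0 * exp(-tsl / t1rho)`. Vectorized over all arguments.
#'
#' @param i0 Baseline intensity at TSL = 0 (>= 0).
#' @param t1rho Relaxation time in ms (> 0).
#' @param tsl Spin-lock time in ms (>= 0).
#' @return Signal intensity, same shape as the broadcast arguments.
#' @examples
#' signal_intensity(100, 50, 50)   # 100 * exp(-1)
#' @export
signal_intensity <- function(i0, t1rho, tsl) {
  if (any(!is.finite(i0)) || any(!is.finite(t1rho)) || any(!is.finite(tsl)))
    stop("inputs must be finite")
  if (any(t1rho <= 0)) stop("'t1rho' must be > 0")
  if (any(i0 < 0)) stop("'i0' must be >= 0")
  if (any(tsl < 0)) stop("'tsl' must be >= 0")
  i0 * exp(-tsl / t1rho)
}

.fit_result <- function(i0_hat, t1rho_hat, residual_norm, converged, clamped) {
  structure(list(i0_hat = i0_hat, t1rho_hat = t1rho_hat,
                 residual_norm = residual_norm, converged = converged,
                 clamped = clamped),
            class = "t1rho_fit")
}

#' @export
print.t1rho_fit <- function(x, ...) {
  cat(sprintf("T1rho fit: t1rho = %.4f ms, i0 = %.4f (residual %.4g, %s%s)\n",
              x$t1rho_hat, x$i0_hat, x$residual_norm,
              if (x$converged) "converged" else "not converged",
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Closed-form two-point T1rho fit
#'
#' Inverts the mono-exponential model from two samples:
#' `t1rho = (tslk - tsl0) / log(i0 / ik)`. When the pair does not decay
#' (`ik >= i0` or `ik <= 0`) no model-conforming solution exists; the estimate
#' is clamped to the upper bound and flagged as not converged.
#'
#' @param i0 Intensity at the earlier spin-lock time `tsl0`.
#' @param ik Intensity at the later spin-lock time `tslk`.
#' @param tsl0,tslk Spin-lock times in ms with `tslk > tsl0 >= 0`.
#' @param bounds Fit bounds from [t1rho_fit_bounds()].
#' @return A `t1rho_fit` with elements `i0_hat` (extrapolated intensity at
#'   TSL = 0), `t1rho_hat` (ms), `residual_norm`, `converged` and `clamped`.
#' @examples
#' two_point_fit(100, 100 * exp(-1), 0, 50)  # t1rho_hat = 50
#' @export
two_point_fit <- function(i0, ik, tsl0, tslk, bounds = t1rho_fit_bounds()) {
  if (any(!is.finite(c(i0, ik, tsl0, tslk)))) stop("inputs must be finite")
  if (tslk <= tsl0 || tsl0 < 0) stop("need tslk > tsl0 >= 0")
  if (i0 < 0 || ik < 0) stop("intensities must be >= 0")
  if (ik <= 0 || ik >= i0) {
    return(.fit_result(i0_hat = i0, t1rho_hat = bounds$upper,
                       residual_norm = 0, converged = FALSE, clamped = TRUE))
  }
  t1 <- (tslk - tsl0) / log(i0 / ik)
  clamped <- FALSE
  if (t1 < bounds$lower) { t1 <- bounds$lower; clamped <- TRUE }
  if (t1 > bounds$upper) { t1 <- bounds$upper; clamped <- TRUE }
  i0_hat <- i0 / exp(-tsl0 / t1)
  pred <- i0_hat * exp(-c(tsl0, tslk) / t1)
  .fit_result(i0_hat = i0_hat, t1rho_hat = t1,
              residual_norm = sqrt(sum((c(i0, ik) - pred)^2)),
              converged = TRUE, clamped = clamped)
}

# Vectorized Levenberg-Marquardt fit of the mono-exponential model.
#
# Y: n_vox x m matrix of intensities; tsls: length-m vector. All voxels are
# iterated simultaneously with per-voxel damping. Initialization is the
# log-linear regression of log(intensity) on tsl (rows with non-positive
# samples are excluded up-front and reported as not converged). The 2x2
# normal equations are solved in closed form. Parameters are projected onto
# [0, i0_max] x [lower, upper] after every accepted step.
.lm_expfit <- function(Y, tsls, bounds = t1rho_fit_bounds(),
                       tol = 1e-8, max_iter = 200L) {
  n <- nrow(Y); m <- length(tsls)
  stopifnot(ncol(Y) == m, m >= 2)
  ok <- rowSums(Y <= 0) == 0 & rowSums(!is.finite(Y)) == 0
  i0_max <- 10 * max(Y, 1e-12)

  i0 <- rep(NA_real_, n); T1 <- rep(NA_real_, n)
  conv <- rep(FALSE, n); clamp <- rep(FALSE, n); rn <- rep(NA_real_, n)

  if (any(ok)) {
    Yk <- Y[ok, , drop = FALSE]
    L <- log(Yk)
    tbar <- mean(tsls); tc <- tsls - tbar
    den <- sum(tc^2)
    slope <- as.vector(L %*% tc) / den
    inter <- rowMeans(L) - slope * tbar
    T0 <- ifelse(slope < -1e-12, -1 / slope, bounds$upper)
    T0 <- pmin(pmax(T0, bounds$lower), bounds$upper)
    A0 <- pmin(pmax(exp(inter), 1e-9), i0_max)

    a <- A0; Tt <- T0
    lam <- rep(1e-3, length(a))
    E <- exp(outer(-1 / Tt, tsls))          # n x m
    R <- Yk - a * E
    sse <- rowSums(R^2)
    active <- rep(TRUE, length(a))
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      ia <- which(active)
      Ei <- E[ia, , drop = FALSE]
      Ri <- R[ia, , drop = FALSE]
      ai <- a[ia]; Ti <- Tt[ia]
      # Jacobian columns: d/d i0 = E ; d/d T = i0 * tsl / T^2 * E
      JT <- (ai / Ti^2) * Ei * rep(tsls, each = length(ia))
      g1 <- rowSums(Ei * Ri)
      g2 <- rowSums(JT * Ri)
      h11 <- rowSums(Ei * Ei)
      h12 <- rowSums(Ei * JT)
      h22 <- rowSums(JT * JT)
      d11 <- h11 * (1 + lam[ia])
      d22 <- h22 * (1 + lam[ia])
      det <- d11 * d22 - h12^2
      det[abs(det) < 1e-300] <- 1e-300
      da <- (d22 * g1 - h12 * g2) / det
      dT <- (d11 * g2 - h12 * g1) / det
      a_new <- pmin(pmax(ai + da, 1e-9), i0_max)
      T_new <- pmin(pmax(Ti + dT, bounds$lower), bounds$upper)
      E_new <- exp(outer(-1 / T_new, tsls))
      R_new <- Yk[ia, , drop = FALSE] - a_new * E_new
      sse_new <- rowSums(R_new^2)
      better <- sse_new <= sse[ia]
      ib <- ia[better]
      if (length(ib)) {
        step <- pmax(abs(a[ib] - a_new[better]) / (abs(a[ib]) + 1e-12),
                     abs(Tt[ib] - T_new[better]) / (abs(Tt[ib]) + 1e-12))
        a[ib] <- a_new[better]; Tt[ib] <- T_new[better]
        E[ib, ] <- E_new[better, , drop = FALSE]
        R[ib, ] <- R_new[better, , drop = FALSE]
        sse[ib] <- sse_new[better]
        lam[ib] <- pmax(lam[ib] / 3, 1e-12)
        active[ib] <- step >= tol
      }
      iw <- ia[!better]
      if (length(iw)) {
        lam[iw] <- lam[iw] * 3
        active[iw] <- lam[iw] < 1e12
      }
    }
    i0[ok] <- a; T1[ok] <- Tt
    conv[ok] <- TRUE
    clamp[ok] <- (Tt <= bounds$lower + 1e-12) | (Tt >= bounds$upper - 1e-12) |
      (a >= i0_max - 1e-9)
    rn[ok] <- sqrt(sse)
  }
  list(i0_hat = i0, t1rho_hat = T1, residual_norm = rn,
       converged = conv, clamped = clamp)
}

#' Multi-point nonlinear least-squares T1rho fit
#'
#' Minimizes `sum_j (I_j - i0 * exp(-tsl_j / t1rho))^2` over `(i0, t1rho)` by
#' Levenberg-Marquardt, initialized from the log-linear regression of
#' `log(I)` on `tsl`. Estimates are constrained to the fit bounds; optima at
#' a bound are flagged `clamped`. With two samples the solution coincides
#' with [two_point_fit()].
#'
#' @param intensities Numeric vector of magnitude intensities, one per TSL.
#' @param tsls Strictly increasing spin-lock times in ms (same length).
#' @param bounds Fit bounds from [t1rho_fit_bounds()].
#' @param tol Relative parameter-step convergence tolerance.
#' @param max_iter Maximum LM iterations.
#' @return A `t1rho_fit` (see [two_point_fit()]).
#' @examples
#' tsls <- c(0, 10, 30, 50)
#' nlls_fit(signal_intensity(100, 40, tsls), tsls)
#' @export
nlls_fit <- function(intensities, tsls, bounds = t1rho_fit_bounds(),
                     tol = 1e-8, max_iter = 200L) {
  if (any(!is.finite(intensities)) || any(!is.finite(tsls)))
    stop("inputs must be finite")
  if (length(intensities) != length(tsls) || length(tsls) < 2)
    stop("need >= 2 samples with matching 'tsls'")
  if (is.unsorted(tsls, strictly = TRUE)) stop("'tsls' must be strictly increasing")
  if (all(intensities == 0)) {
    return(.fit_result(0, bounds$upper, 0, converged = FALSE, clamped = TRUE))
  }
  # No decay representable by the model: report the upper-bound clamp directly
  # (the LM path would reach the same point).
  fit <- .lm_expfit(matrix(intensities, nrow = 1), tsls, bounds, tol, max_iter)
  .fit_result(fit$i0_hat[1], fit$t1rho_hat[1], fit$residual_norm[1],
              fit$converged[1], fit$clamped[1])
}

#' Voxelwise T1rho map from a set of weighted volumes
#'
#' Applies [nlls_fit()] (vectorized over voxels) or [two_point_fit()] to every
#' voxel of the ROI (or the whole grid when `roi` is `NULL`). Volume contrasts
#' must match the protocol TSLs in order; a PD-weighted volume is accepted in
#' the slot of TSL = 0, in which case the map is flagged model-nonconforming
#' (the mono-exponential model does not link PD-weighted contrast to T1rho).
#'
#' @param volumes List of [weighted_volume()] objects, one per protocol TSL.
#' @param protocol A [t1rho_protocol()].
#' @param roi Optional [roi_mask()] (or integer array); voxels with label 0
#'   are skipped. `NULL` fits every voxel.
#' @param method `"nlls"` or `"two_point"` (the latter requires exactly two
#'   volumes).
#' @param bounds Fit bounds from [t1rho_fit_bounds()].
#' @return A `t1rho_map`: list with `values` (3D array, ms; 0 where invalid),
#'   `valid` (3D logical) and fit metadata. Voxels with any non-positive
#'   sample are marked invalid rather than fitted.
#' @export
fit_volume <- function(volumes, protocol, roi = NULL,
                       method = c("nlls", "two_point"),
                       bounds = t1rho_fit_bounds()) {
  method <- match.arg(method)
  stopifnot(inherits(protocol, "t1rho_protocol"))
  if (!is.list(volumes) || !all(vapply(volumes, inherits, TRUE, "weighted_volume")))
    stop("'volumes' must be a list of weighted_volume objects")
  if (length(volumes) != length(protocol$tsls))
    stop("number of volumes must match the protocol TSL count")
  dims <- dim(volumes[[1]]$data)
  if (!all(vapply(volumes, function(v) identical(dim(v$data), dims), TRUE)))
    stop("all volumes must share the same grid shape")
  nonconforming <- FALSE
  for (j in seq_along(volumes)) {
    v <- volumes[[j]]
    if (v$contrast == "pd") {
      if (protocol$tsls[j] != 0)
        stop("a PD-weighted volume may only stand in for the TSL = 0 contrast")
      nonconforming <- TRUE
    } else if (!isTRUE(all.equal(v$tsl, protocol$tsls[j]))) {
      stop(sprintf("volume %d is tagged TSL %g ms but the protocol expects %g ms",
                   j, v$tsl, protocol$tsls[j]))
    }
  }
  if (method == "two_point" && length(volumes) != 2)
    stop("method 'two_point' requires exactly two volumes")

  roi_arr <- if (is.null(roi)) NULL else roi_labels(roi)
  if (!is.null(roi_arr) && !identical(dim(roi_arr), dims))
    stop("'roi' shape must match the volumes")
  sel <- if (is.null(roi_arr)) rep(TRUE, prod(dims)) else as.vector(roi_arr > 0)

  values <- array(0, dims); valid <- array(FALSE, dims)
  if (any(sel)) {
    Y <- vapply(volumes, function(v) as.vector(v$data)[sel],
                numeric(sum(sel)))
    Y <- matrix(Y, ncol = length(volumes))
    if (method == "two_point") {
      i0 <- Y[, 1]; ik <- Y[, 2]
      t0 <- protocol$tsls[1]; tk <- protocol$tsls[2]
      decays <- ik > 0 & ik < i0
      t1 <- rep(bounds$upper, nrow(Y))
      t1[decays] <- (tk - t0) / log(i0[decays] / ik[decays])
      t1 <- pmin(pmax(t1, bounds$lower), bounds$upper)
      conv <- decays & i0 > 0
    } else {
      fit <- .lm_expfit(Y, protocol$tsls, bounds)
      t1 <- fit$t1rho_hat
      conv <- fit$converged
      t1[!conv] <- 0
    }
    vvec <- as.vector(values); bvec <- as.vector(valid)
    idx <- which(sel)
    vvec[idx[conv]] <- t1[conv]
    bvec[idx] <- conv
    values <- array(vvec, dims); valid <- array(bvec, dims)
  }
  structure(list(values = values, valid = valid, method = method,
                 bounds = bounds, nonconforming = nonconforming),
            class = "t1rho_map")
}

#' Construct a T1rho map object directly
#'
#' @param values 3D array of T1rho values in ms.
#' @param valid 3D logical array marking trusted voxels.
#' @return A `t1rho_map`.
#' @export
t1rho_map <- function(values, valid = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (is.null(valid)) valid <- array(TRUE, dim(values))
  stopifnot(identical(dim(valid), dim(values)))
  if (any(!is.finite(values[valid]))) stop("values must be finite where valid")
  structure(list(values = values, valid = as.array(valid > 0),
                 method = "direct", bounds = NULL, nonconforming = FALSE),
            class = "t1rho_map")
}

#' @export
print.t1rho_map <- function(x, ...) {
  cat(sprintf("t1rho_map: %s voxels, %d valid (%s)%s\n",
              paste(dim(x$values), collapse = " x "), sum(x$valid), x$method,
              if (isTRUE(x$nonconforming)) ", model-nonconforming inputs" else ""))
  invisible(x)
}
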