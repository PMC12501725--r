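#' Sliding-window tiling plan
#'
#' Window start positions along one axis: every `stride` pixels plus a final
#' window flush with the edge, so every pixel is covered by at least one
#' window for any `stride <= window`.
#'
#' @param extent Axis length in pixels.
#' @param window Window edge (default 64).
#' @param stride Step between windows, `1 <= stride <= window`.
#' @return Integer vector of 1-based window start positions.
#' @export
tile_starts <- function(extent, window = 64L, stride = 32L) {
  stopifnot(stride >= 1, stride <= window)
  if (extent <= window) return(1L)
  unique(c(seq(1L, extent - window + 1L, by = stride), extent - window + 1L))
}

# reflect-pad a matrix up to (h, w)
.reflect_pad <- function(m, h, w) {
  if (nrow(m) < h) {
    need <- h - nrow(m)
    m <- rbind(m, m[nrow(m):(nrow(m) - need + 1L), , drop = FALSE])
  }
  if (ncol(m) < w) {
    need <- w - ncol(m)
    m <- cbind(m, m[, ncol(m):(ncol(m) - need + 1L), drop = FALSE])
  }
  m
}

# Dispatch a (B, 2, ps, ps) batch through a patch model; plain functions are
# accepted as stub models in tests.
.predict_patch_batch <- function(model, x) {
  if (is.function(model)) model(x)
  else if (inherits(model, "t1rho_unet")) unet_forward(model, x, train = FALSE)
  else stop("not a patch model")
}

.predict_rows <- function(model, x) {
  if (is.function(model)) model(x)
  else if (inherits(model, "t1rho_mlp")) mlp_forward(model, x, train = FALSE)
  else stop("not a voxel model")
}

# Accept either a make_training_set() entry or a list of two weighted
# volumes (I0-like first); returns normalized channel arrays + roi labels.
.as_entry <- function(volumes, roi) {
  if (is.list(volumes) && !is.null(volumes$x1)) return(volumes)
  stopifnot(length(volumes) == 2)
  a1 <- if (inherits(volumes[[1]], "weighted_volume")) volumes[[1]]$data else volumes[[1]]
  a2 <- if (inherits(volumes[[2]], "weighted_volume")) volumes[[2]]$data else volumes[[2]]
  lab <- roi_labels(roi)
  scale <- .norm_scale(a1, lab)
  list(x1 = a1 / scale, x2 = a2 / scale, roi = lab,
       slices = which(apply(lab > 0, 1, any)))
}

#' Whole-volume U-Net inference by sliding window
#'
#' Every pixel of every ROI-containing slice is covered by at least one
#' 64x64 window; overlapping window predictions are averaged per pixel.
#' Slices smaller than the window are reflect-padded and the prediction is
#' cropped back. Output values lie in the limiter range; the validity mask is
#' `roi > 0` (non-ROI voxels are reported as 0).
#'
#' @param model A trained `t1rho_unet` (or a stub function mapping a
#'   `(B, 2, w, w)` array to a `(B, w, w)` array).
#' @param volumes A [make_training_set()] entry or a list of the two input
#'   volumes (I0-like first).
#' @param roi A [roi_mask()].
#' @param stride Window stride in pixels (default 32, half-window overlap).
#' @param window Window edge in pixels.
#' @return A `t1rho_map`.
#' @export
sliding_window_map <- function(model, volumes, roi, stride = 32L, window = 64L) {
  entry <- .as_entry(volumes, roi)
  lab <- roi_labels(roi)
  dims <- dim(entry$x1)
  H <- dims[2]; W <- dims[3]
  values <- array(0, dims)
  slices <- entry$slices
  Hp <- max(H, window); Wp <- max(W, window)
  rs <- tile_starts(Hp, window, stride)
  cs <- tile_starts(Wp, window, stride)
  grid <- expand.grid(r = rs, c = cs)
  for (s in slices) {
    m1 <- .reflect_pad(entry$x1[s, , ], Hp, Wp)
    m2 <- .reflect_pad(entry$x2[s, , ], Hp, Wp)
    acc <- matrix(0, Hp, Wp); cnt <- matrix(0, Hp, Wp)
    for (b0 in seq(1, nrow(grid), by = 16L)) {
      idx <- b0:min(b0 + 15L, nrow(grid))
      B <- length(idx)
      xb <- array(0, c(B, 2, window, window))
      for (q in seq_len(B)) {
        rr <- grid$r[idx[q]]:(grid$r[idx[q]] + window - 1L)
        cc <- grid$c[idx[q]]:(grid$c[idx[q]] + window - 1L)
        xb[q, 1, , ] <- m1[rr, cc]; xb[q, 2, , ] <- m2[rr, cc]
      }
      pb <- .predict_patch_batch(model, xb)
      for (q in seq_len(B)) {
        rr <- grid$r[idx[q]]:(grid$r[idx[q]] + window - 1L)
        cc <- grid$c[idx[q]]:(grid$c[idx[q]] + window - 1L)
        acc[rr, cc] <- acc[rr, cc] + pb[q, , ]
        cnt[rr, cc] <- cnt[rr, cc] + 1
      }
    }
    values[s, , ] <- (acc / cnt)[seq_len(H), seq_len(W)]
  }
  values[lab == 0] <- 0
  t1rho_map(values, lab > 0)
}

#' Whole-volume MLP inference over ROI voxels
#'
#' Extracts the `(I0-like, Ik-like)` intensity pair of every ROI voxel, runs
#' the voxel model, and reassembles predictions at their exact voxel
#' positions. Non-ROI voxels are invalid (0).
#'
#' @param model A trained `t1rho_mlp` (or a stub function mapping an `n x 2`
#'   matrix to `n` values).
#' @param volumes A [make_training_set()] entry or a list of the two input
#'   volumes (I0-like first).
#' @param roi A non-empty [roi_mask()].
#' @return A `t1rho_map`.
#' @export
voxelwise_map <- function(model, volumes, roi) {
  entry <- .as_entry(volumes, roi)
  lab <- roi_labels(roi)
  sel <- which(lab > 0)
  if (!length(sel)) stop("empty ROI")
  X <- cbind(entry$x1[sel], entry$x2[sel])
  preds <- numeric(length(sel))
  for (b0 in seq(1, length(sel), by = 8192L)) {
    idx <- b0:min(b0 + 8191L, length(sel))
    preds[idx] <- .predict_rows(model, X[idx, , drop = FALSE])
  }
  values <- array(0, dim(lab))
  values[sel] <- preds
  t1rho_map(values, lab > 0)
}
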