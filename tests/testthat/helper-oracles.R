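# Independent oracles and small fixtures used across the suite.

# Dense grid search for the mono-exponential fit, profiled over i0: for a
# fixed t1rho the optimal i0 is the closed-form linear least-squares
# solution, so a dense 1D grid over t1rho (step 0.05 ms) scans the same
# objective as a 2D grid at that resolution.
grid_search_fit <- function(intensities, tsls, t1_lo = 5, t1_hi = 150,
                            step = 0.05) {
  grid <- seq(t1_lo, t1_hi, by = step)
  E <- exp(outer(-tsls, grid, "/"))        # m x G, entries exp(-tsl/t1rho)
  num <- as.vector(intensities %*% E)
  den <- colSums(E * E)
  i0 <- num / den
  sse <- sum(intensities^2) - i0 * num     # ||y||^2 - 2 i0 y.E + i0^2 E.E
  j <- which.min(sse)
  list(i0 = i0[j], t1rho = grid[j], step = step)
}

# Pure-R double-precision reference for the 3x3 same-padding convolution
# (activation layout: rows = (b, r, c) with c fastest, cols = channels).
ref_conv3x3 <- function(X, Wt, B, H, W) {
  cin <- ncol(X); cout <- ncol(Wt)
  Y <- matrix(0, nrow(X), cout)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  for (k in 1:9) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    Wk <- Wt[((k - 1) * cin + 1):(k * cin), , drop = FALSE]
    for (b in seq_len(B)) {
      for (r in seq_len(H)) {
        r2 <- r + dy
        if (r2 < 1 || r2 > H) next
        cs <- max(1, 1 - dx):min(W, W - dx)
        n <- (b - 1) * H * W + (r - 1) * W + cs
        n2 <- (b - 1) * H * W + (r2 - 1) * W + cs + dx
        Y[n, ] <- Y[n, ] + X[n2, , drop = FALSE] %*% Wk
      }
    }
  }
  Y
}

# Small, quick phantom used by most tests.
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(4, 64, 64), n_slices_with_cartilage = 2,
               seed = seed, ...)
}

small_cohort <- function(n = 2, seed = 1, snr = 30,
                         protocol = t1rho_protocol(c(0, 10, 30, 50))) {
  generate_cohort(n, small_spec(seed = seed, snr = snr), protocol, seed = seed)
}

nlls_truth_maps <- function(cohort) {
  tm <- lapply(cohort, function(s) fit_volume(s$volumes, s$protocol,
                                              method = "nlls"))
  names(tm) <- vapply(cohort, function(s) s$id, "")
  tm
}
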