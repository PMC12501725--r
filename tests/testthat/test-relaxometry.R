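test_that("signal model evaluates the mono-exponential decay", {
  expect_equal(signal_intensity(100, 50, 50), 100 * exp(-1), tolerance = 1e-12)
  expect_equal(signal_intensity(100, 37.2, 0), 100)
  # cohort-mean T1rho of 45.36 ms at TSL 10
  expect_equal(signal_intensity(80, 45.36, 10), 80 * exp(-10 / 45.36),
               tolerance = 1e-12)
  expect_error(signal_intensity(100, -5, 10), "t1rho")
  expect_error(signal_intensity(100, 0, 10), "t1rho")
})

test_that("signal is strictly decreasing in TSL and equals i0 at TSL 0", {
  set.seed(11)
  for (i in 1:50) {
    i0 <- runif(1, 10, 200); t1 <- runif(1, 5, 120)
    tsl <- sort(runif(6, 0.1, 80))
    v <- signal_intensity(i0, t1, c(0, tsl))
    expect_equal(v[1], i0)
    expect_true(all(diff(v) < 0))
  }
})

test_that("two-point fit inverts the signal model exactly", {
  f <- two_point_fit(100, 100 * exp(-1), 0, 50)
  expect_equal(f$t1rho_hat, 50, tolerance = 1e-12)
  expect_true(f$converged)
  # non-zero first TSL: 20 / log(100 / 67.0320) with log term 0.4
  f2 <- two_point_fit(100, 67.0320, 10, 30)
  expect_equal(log(100 / 67.0320), 0.4, tolerance = 1e-5)
  expect_equal(f2$t1rho_hat, 50, tolerance = 1e-4)
})

test_that("two-point fit is the identity on noise-free model signals", {
  set.seed(7)
  for (i in 1:1000) {
    i0 <- runif(1, 20, 300); t1 <- runif(1, 2, 400)
    tsl0 <- runif(1, 0, 20); tslk <- tsl0 + runif(1, 5, 60)
    ik <- signal_intensity(i0, t1, tslk)
    ia <- signal_intensity(i0, t1, tsl0)
    f <- two_point_fit(ia, ik, tsl0, tslk)
    expect_equal(f$t1rho_hat, t1, tolerance = 1e-9)
  }
})

test_that("non-decaying pairs are clamped and flagged", {
  f <- two_point_fit(50, 55, 0, 50)
  expect_false(f$converged)
  expect_true(f$clamped)
  expect_equal(f$t1rho_hat, t1rho_fit_bounds()$upper)
  f2 <- two_point_fit(50, 0, 0, 50)
  expect_false(f2$converged)
})

test_that("NLLS recovers noise-free parameters and matches the 2-point form", {
  tsls <- c(0, 10, 30, 50)
  f <- nlls_fit(signal_intensity(100, 40, tsls), tsls)
  expect_equal(f$i0_hat, 100, tolerance = 1e-6)
  expect_equal(f$t1rho_hat, 40, tolerance = 1e-6)
  expect_true(f$converged)
  set.seed(3)
  for (i in 1:25) {
    i0 <- runif(1, 50, 200); t1 <- runif(1, 10, 120)
    y <- signal_intensity(i0, t1, c(0, 50)) * runif(2, 0.9, 1.1)
    if (y[2] >= y[1]) next
    a <- nlls_fit(y, c(0, 50))
    b <- two_point_fit(y[1], y[2], 0, 50)
    expect_equal(a$t1rho_hat, b$t1rho_hat, tolerance = 1e-6)
  }
})

test_that("NLLS degenerate inputs are reported honestly", {
  tsls <- c(0, 10, 30, 50)
  f <- nlls_fit(c(100, 100, 100, 100), tsls)
  expect_true(f$clamped)
  expect_equal(f$t1rho_hat, t1rho_fit_bounds()$upper)
  f0 <- nlls_fit(c(0, 0, 0, 0), tsls)
  expect_false(f0$converged)
  expect_error(nlls_fit(c(100, NA, 50, 20), tsls), "finite")
  expect_error(nlls_fit(c(100, 50), c(10, 5)), "increasing")
})

test_that("NLLS agrees with the dense grid-search oracle on noisy samples", {
  tsls <- c(0, 10, 30, 50)
  set.seed(21)
  for (i in 1:100) {
    i0 <- runif(1, 60, 140); t1 <- runif(1, 10, 120)
    clean <- signal_intensity(i0, t1, tsls)
    sigma <- i0 / 30
    y <- sqrt((clean + rnorm(4, 0, sigma))^2 + rnorm(4, 0, sigma)^2)
    fit <- nlls_fit(y, tsls)
    oracle <- grid_search_fit(y, tsls)
    expect_lte(abs(fit$t1rho_hat - oracle$t1rho), oracle$step + 1e-9)
  }
})

test_that("NLLS matches an independent Levenberg-Marquardt implementation", {
  skip_if_not_installed("minpack.lm")
  tsls <- c(0, 10, 30, 50)
  set.seed(5)
  for (i in 1:20) {
    i0 <- runif(1, 60, 140); t1 <- runif(1, 15, 100)
    y <- abs(signal_intensity(i0, t1, tsls) + rnorm(4, 0, i0 / 25))
    mine <- nlls_fit(y, tsls)
    ref <- minpack.lm::nlsLM(y ~ a * exp(-tsls / T),
                             start = list(a = max(y), T = 50),
                             lower = c(1e-6, 1), upper = c(1e6, 500))
    expect_equal(mine$t1rho_hat, unname(coef(ref)["T"]), tolerance = 1e-4)
    expect_equal(mine$i0_hat, unname(coef(ref)["a"]), tolerance = 1e-4)
  }
})

test_that("fit_volume reproduces the generating field on a noise-free phantom", {
  spec <- small_spec(seed = 4, snr = Inf)
  proto <- t1rho_protocol(c(0, 10, 30, 50))
  f <- make_t1rho_field(spec)
  vols <- render_weighted_volumes(f, f$roi, proto, spec)
  m <- fit_volume(vols, proto, roi = f$roi, method = "nlls")
  sel <- f$roi$labels > 0
  expect_lt(max(abs(m$values[sel] - f$t1rho[sel])), 1e-6)
  expect_true(all(m$valid[sel]))
})

test_that("two-point volume fitting equals the per-voxel closed form", {
  spec <- small_spec(seed = 6)
  proto2 <- t1rho_protocol(c(0, 50))
  f <- make_t1rho_field(spec)
  vols <- render_weighted_volumes(f, f$roi, proto2, spec)
  m <- fit_volume(vols, proto2, roi = f$roi, method = "two_point")
  sel <- which(f$roi$labels > 0)
  for (j in sample(sel, 50)) {
    ref <- two_point_fit(vols[[1]]$data[j], vols[[2]]$data[j], 0, 50)
    if (ref$converged)
      expect_equal(m$values[j], ref$t1rho_hat, tolerance = 1e-12)
  }
})

test_that("fit_volume validates shapes, contrasts and empty ROIs", {
  spec <- small_spec(seed = 8)
  proto <- t1rho_protocol(c(0, 10, 30, 50))
  f <- make_t1rho_field(spec)
  vols <- render_weighted_volumes(f, f$roi, proto, spec)
  expect_error(fit_volume(vols[1:3], proto), "match")
  bad <- vols; bad[[2]] <- weighted_volume(bad[[2]]$data, 99)
  expect_error(fit_volume(bad, proto), "protocol expects")
  empty <- roi_mask(array(0L, dim(f$t1rho)))
  m <- fit_volume(vols, proto, roi = empty)
  expect_false(any(m$valid))
})

test_that("fitting a PD surrogate as I0 biases the regional T1rho estimate", {
  spec <- small_spec(seed = 9)
  proto <- t1rho_protocol(c(0, 10, 30, 50))
  co <- generate_cohort(2, spec, proto, seed = 9)
  proto2 <- t1rho_protocol(c(0, 50))
  err <- function(m, sub) {
    sel <- roi_labels(sub$roi) > 0 & m$valid
    abs(mean(m$values[sel]) - mean(sub$truth$values[sel]))
  }
  for (sub in co) {
    tsl0 <- sub$volumes[[1]]; tsl50 <- sub$volumes[[4]]
    m_true <- fit_volume(list(tsl0, tsl50), proto2, roi = sub$roi)
    m_pd <- fit_volume(list(sub$pd_volume, tsl50), proto2, roi = sub$roi)
    expect_true(m_pd$nonconforming)
    expect_gt(err(m_pd, sub), err(m_true, sub))
  }
})
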