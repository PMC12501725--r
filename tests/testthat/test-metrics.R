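mk_map <- function(vals, valid = NULL) {
  arr <- array(vals, c(1, 1, length(vals)))
  t1rho_map(arr, if (is.null(valid)) NULL else array(valid, dim(arr)))
}
mk_roi <- function(labels) roi_mask(array(as.integer(labels),
                                          c(1, 1, length(labels))))

test_that("hand-computed metric examples are exact", {
  roi <- mk_roi(c(1, 1, 1))
  m <- compute_subject_metrics(mk_map(c(44, 55, 66)), mk_map(c(40, 50, 60)), roi)
  expect_equal(m$mae, 5, tolerance = 1e-12)
  expect_equal(m$mape, 10, tolerance = 1e-12)
  expect_equal(m$re, 5, tolerance = 1e-12)
  expect_equal(m$rpe, 10, tolerance = 1e-12)
  expect_equal(m$bias, 5, tolerance = 1e-12)
  expect_equal(m$pct_bias, 10, tolerance = 1e-12)
  expect_equal(m$n_voxels, 3)
  # opposite-signed voxel errors: regional error collapses, voxelwise stays
  roi2 <- mk_roi(c(1, 1))
  m2 <- compute_subject_metrics(mk_map(c(45, 55)), mk_map(c(40, 60)), roi2)
  expect_equal(m2$mae, 5, tolerance = 1e-12)
  expect_equal(m2$mape, 100 * (5 / 40 + 5 / 60) / 2, tolerance = 1e-12)
  expect_equal(m2$re, 0, tolerance = 1e-12)
  expect_equal(m2$rpe, 0, tolerance = 1e-12)
  expect_equal(m2$bias, 0, tolerance = 1e-12)
})

test_that("identity prediction gives all-zero errors", {
  y <- runif(20, 30, 70)
  m <- compute_subject_metrics(mk_map(y), mk_map(y), mk_roi(rep(1, 20)))
  expect_true(all(abs(unlist(m[c("mae", "mape", "re", "rpe", "bias",
                                 "pct_bias")])) < 1e-12))
})

test_that("regional error never exceeds the voxelwise error", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    y <- runif(n, 20, 80); yh <- y + rnorm(n, 0, 10)
    m <- compute_subject_metrics(mk_map(yh), mk_map(y), mk_roi(rep(1, n)))
    expect_lte(m$re, m$mae + 1e-12)
    expect_equal(m$rpe, 100 * m$re / mean(y), tolerance = 1e-12)
    expect_equal(sign(m$pct_bias), sign(m$bias))
    expect_equal(abs(m$bias), m$re, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to voxel order and non-selected voxels", {
  set.seed(62)
  y <- runif(30, 30, 70); yh <- y + rnorm(30, 0, 5)
  lab <- rep(c(1L, 0L), 15)
  m1 <- compute_subject_metrics(mk_map(yh), mk_map(y), mk_roi(lab))
  yh2 <- yh; yh2[lab == 0] <- -99; y2 <- y; y2[lab == 0] <- 1e6
  m2 <- compute_subject_metrics(mk_map(yh2), mk_map(y2), mk_roi(lab))
  expect_equal(m1, m2)
  perm <- sample(30)
  m3 <- compute_subject_metrics(mk_map(yh[perm]), mk_map(y[perm]),
                                mk_roi(lab[perm]))
  expect_equal(m1[-7], m3[-7])
  expect_error(compute_subject_metrics(mk_map(yh), mk_map(y),
                                       mk_roi(rep(0, 30))), "empty")
  expect_error(compute_subject_metrics(mk_map(yh), mk_map(-y),
                                       mk_roi(rep(1, 30))), "positive")
})

test_that("subregion reporting covers each labeled region", {
  set.seed(63)
  lab <- c(rep(1, 5), rep(2, 5), rep(3, 5), rep(4, 5))
  y <- runif(20, 30, 70); yh <- y + rnorm(20, 0, 3)
  r <- compute_region_metrics(mk_map(yh), mk_map(y), mk_roi(lab))
  expect_setequal(r$region, c("all", "1", "2", "3", "4"))
  expect_equal(r$n_voxels[r$region == "all"], 20)
  expect_equal(r$n_voxels[r$region == "2"], 5)
})

test_that("cohort summary matches an independent two-pass computation", {
  set.seed(64)
  reports <- lapply(1:20, function(i) {
    n <- sample(10:30, 1)
    y <- runif(n, 30, 70); yh <- y + rnorm(n, 0, 5)
    compute_subject_metrics(mk_map(yh), mk_map(y), mk_roi(rep(1, n)))
  })
  s <- summarize_cohort(reports)
  df <- do.call(rbind, reports)
  for (met in s$metric) {
    v <- df[[met]]
    expect_equal(s$mean[s$metric == met], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(s$sd[s$metric == met],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)), tolerance = 1e-12)
  }
  expect_equal(attr(s, "cohort_bias"), mean(df$bias), tolerance = 1e-12)
  # |cohort bias| is bounded by the mean regional error
  expect_lte(abs(attr(s, "cohort_bias")),
             s$mean[s$metric == "re"] + 1e-12)
  # sign cancellation across subjects
  two <- list(transform(reports[[1]], bias = 2, re = 2),
              transform(reports[[2]], bias = -2, re = 2))
  s2 <- summarize_cohort(two)
  expect_equal(attr(s2, "cohort_bias"), 0)
  expect_equal(s2$mean[s2$metric == "re"], 2)
  # single report: SD 0 by convention
  s1 <- summarize_cohort(reports[1])
  expect_true(all(s1$sd == 0))
  expect_error(summarize_cohort(list()), "no reports")
})

test_that("SSIM within the ROI is 1 for identical volumes and symmetric", {
  set.seed(65)
  a <- array(runif(2 * 40 * 40, 0, 100), c(2, 40, 40))
  b <- a + array(rnorm(length(a), 0, 5), dim(a))
  roi <- roi_mask(array(rbinom(length(a), 1, 0.3), dim(a)))
  expect_equal(ssim_roi(a, a, roi), 1, tolerance = 1e-9)
  expect_equal(ssim_roi(a, b, roi), ssim_roi(b, a, roi), tolerance = 1e-12)
  expect_lt(ssim_roi(a, b, roi), 1)
  expect_error(ssim_roi(a, b, roi_mask(array(0L, dim(a)))), "empty")
})

test_that("SSIM of independent noise volumes is near zero", {
  set.seed(66)
  a <- array(rnorm(6 * 60 * 60), c(6, 60, 60))
  b <- array(rnorm(6 * 60 * 60), c(6, 60, 60))
  roi <- roi_mask(array(1L, dim(a)))   # > 10^4 ROI voxels
  expect_lt(abs(ssim_roi(a, b, roi)), 0.1)
})
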