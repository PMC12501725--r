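# The layer engine is the package's own numerical core, so it gets its own
# correctness suite: parity with a double-precision reference convolution,
# numeric gradient checks through the full models, and exactness of the
# pooling / upsampling operators.

test_that("compiled convolution matches the pure-R reference", {
  set.seed(31)
  for (case in list(c(2, 2, 3, 6, 8), c(1, 4, 2, 8, 8), c(3, 3, 5, 10, 6))) {
    B <- case[1]; cin <- case[2]; cout <- case[3]; H <- case[4]; W <- case[5]
    X <- matrix(rnorm(B * H * W * cin), ncol = cin)
    Wt <- matrix(rnorm(9 * cin * cout, 0, 0.5), 9 * cin, cout)
    got <- t1rhomap:::.conv3x3_fwd_cpp(X, Wt, B, H, W)
    want <- ref_conv3x3(X, Wt, B, H, W)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("convolution backward is consistent with the forward map", {
  # linear operator: dX must equal the transpose action; checked against
  # finite differences of the double-precision reference
  set.seed(32)
  B <- 2; cin <- 2; cout <- 3; H <- 6; W <- 5
  X <- matrix(rnorm(B * H * W * cin), ncol = cin)
  Wt <- matrix(rnorm(9 * cin * cout, 0, 0.5), 9 * cin, cout)
  dY <- matrix(rnorm(B * H * W * cout), ncol = cout)
  bw <- t1rhomap:::.conv3x3_bwd_cpp(X, Wt, dY, B, H, W)
  # <conv(X), dY> gradients: dW via directional finite differences
  f <- function(Wmod) sum(ref_conv3x3(X, Wmod, B, H, W) * dY)
  eps <- 1e-4
  for (i in sample(length(Wt), 6)) {
    Wp <- Wt; Wp[i] <- Wp[i] + eps
    Wm <- Wt; Wm[i] <- Wm[i] - eps
    expect_equal(bw$dW[i], (f(Wp) - f(Wm)) / (2 * eps), tolerance = 1e-2)
  }
  g <- function(Xmod) sum(ref_conv3x3(Xmod, Wt, B, H, W) * dY)
  for (i in sample(length(X), 6)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    expect_equal(bw$dX[i], (g(Xp) - g(Xm)) / (2 * eps), tolerance = 1e-2)
  }
})

test_that("U-Net backward matches numeric gradients", {
  set.seed(33)
  m <- build_unet(unet_config(depth = 2, base_channels = 3, patch_size = 8,
                              seed = 7))
  B <- 2
  x <- array(runif(B * 2 * 64, 0.2, 1.5), c(B, 2, 8, 8))
  t <- array(runif(B * 64, 20, 90), c(B, 8, 8))
  w <- array(rbinom(B * 64, 1, 0.7), c(B, 8, 8))
  lossfun <- function() {
    p <- unet_forward(m, x, train = TRUE)
    l1_loss(p, t, w)$loss
  }
  p <- unet_forward(m, x, train = TRUE)
  unet_backward(m, l1_loss(p, t, w)$grad)
  eps <- 1e-4
  checked <- 0
  for (ly in m$layers) for (pn in ly$params) {
    g <- ly[[paste0("g", pn)]]
    for (i in sample(length(ly[[pn]]), min(2, length(ly[[pn]])))) {
      w0 <- ly[[pn]][i]
      ly[[pn]][i] <- w0 + eps; lp <- lossfun()
      ly[[pn]][i] <- w0 - eps; lm <- lossfun()
      ly[[pn]][i] <- w0
      num <- (lp - lm) / (2 * eps)
      if (abs(num) > 1e-3) {      # skip L1/ReLU kink crossings
        expect_equal(g[i], num, tolerance = 0.05)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 10)
})

test_that("MLP backward matches numeric gradients", {
  set.seed(34)
  m <- build_mlp(mlp_config(n_blocks = 3, width = 8, seed = 3))
  X <- matrix(runif(40, 0.1, 1.2), 20, 2)
  y <- runif(20, 20, 90)
  lossfun <- function() l1_loss(mlp_forward(m, X, train = TRUE), y)$loss
  mlp_backward(m, l1_loss(mlp_forward(m, X, train = TRUE), y)$grad)
  eps <- 1e-6
  checked <- 0
  for (ly in m$layers) for (pn in ly$params) {
    g <- ly[[paste0("g", pn)]]
    for (i in sample(length(ly[[pn]]), min(2, length(ly[[pn]])))) {
      w0 <- ly[[pn]][i]
      ly[[pn]][i] <- w0 + eps; lp <- lossfun()
      ly[[pn]][i] <- w0 - eps; lm <- lossfun()
      ly[[pn]][i] <- w0
      num <- (lp - lm) / (2 * eps)
      if (abs(num) > 1e-4) {
        expect_equal(g[i], num, tolerance = 1e-3)
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 10)
})

test_that("max pooling picks the maximum and routes gradients to it", {
  set.seed(35)
  B <- 2; H <- 4; W <- 4
  X <- matrix(rnorm(B * H * W * 2), ncol = 2)
  st <- new.env()
  g <- t1rhomap:::.get_geom(B, H, W)
  Y <- maxpool_forward(st, X, g)
  arr <- t1rhomap:::.mat_to_arr(X, B, H, W)
  want <- apply(arr, c(1, 2), function(m) {
    m <- matrix(m, H, W)
    as.vector(t(sapply(seq(1, H, 2), function(r)
      sapply(seq(1, W, 2), function(c) max(m[r:(r + 1), c:(c + 1)])))))
  })
  Yarr <- t1rhomap:::.mat_to_arr(Y, B, H / 2, W / 2)
  for (b in 1:B) for (ch in 1:2)
    expect_equal(sort(as.vector(Yarr[b, ch, , ])), sort(want[, b, ch]))
  dY <- matrix(1, nrow(Y), 2)
  dX <- maxpool_backward(st, dY, g)
  expect_equal(colSums(dX), colSums(dY))      # gradient mass conserved
  expect_true(all(dX %in% c(0, 1)))
})

test_that("bilinear upsampling doubles resolution and preserves constants", {
  B <- 1; h <- 4; w <- 4
  X <- matrix(2.5, h * w, 3)
  Y <- upsample_forward(X, B, h, w)
  expect_equal(dim(Y), c(4 * h * w, 3))
  expect_equal(max(abs(Y - 2.5)), 0, tolerance = 1e-12)
  # adjoint property: <U x, y> == <x, U^T y>
  set.seed(36)
  X <- matrix(rnorm(h * w), h * w, 1)
  dY <- matrix(rnorm(4 * h * w), 4 * h * w, 1)
  lhs <- sum(upsample_forward(X, B, h, w) * dY)
  rhs <- sum(X * upsample_backward(dY, B, h, w))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
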