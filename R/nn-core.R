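# Minimal deterministic neural-network engine.
#
# Activations for 2D layers are stored as dense matrices of shape
# (B*H*W) x C with row index n = (b-1)*H*W + (r-1)*W + c (column fastest),
# so convolutions become a handful of BLAS GEMMs on index-shifted copies
# (an im2col by row indexing). All randomness goes through R's RNG and all
# linear algebra through the sequential BLAS, so results are reproducible
# for a fixed seed.

.nn_cache <- new.env(parent = emptyenv())

# (B, C, H, W) array <-> stacked matrix
.arr_to_mat <- function(arr) {
  d <- dim(arr)  # B C H W
  matrix(aperm(arr, c(4, 3, 1, 2)), nrow = d[1] * d[3] * d[4], ncol = d[2])
}
.mat_to_arr <- function(X, B, H, W) {
  C <- ncol(X)
  aperm(array(X, c(W, H, B, C)), c(3, 4, 2, 1))
}

# Index geometry for one (B, H, W) activation grid (max-pool indices; the
# convolutions run in compiled code and need no index tables).
.get_geom <- function(B, H, W) {
  key <- paste(B, H, W, sep = "x")
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  N <- B * H * W
  pidx <- NULL
  if (H %% 2 == 0 && W %% 2 == 0) {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    r1 <- rep(seq_len(H2) * 2L - 1L, each = W2)
    c1 <- rep(seq_len(W2) * 2L - 1L, H2)
    boff2 <- rep((seq_len(B) - 1L) * H * W, each = H2 * W2)
    at <- function(dr, dc) as.integer(rep((r1 + dr - 1L) * W + (c1 + dc), B) + boff2)
    pidx <- list(at(0L, 0L), at(0L, 1L), at(1L, 0L), at(1L, 1L))
  }
  g <- list(B = B, H = H, W = W, N = N, pidx = pidx)
  .nn_cache[[key]] <- g
  g
}

# Sparse operator for 2x bilinear upsampling (align-corners = FALSE),
# cached per (B, h, w).
.get_upsample <- function(B, h, w) {
  key <- paste("up", B, h, w, sep = "x")
  U <- .nn_cache[[key]]
  if (!is.null(U)) return(U)
  axis_mat <- function(n) {
    i <- j1 <- j2 <- w1 <- w2 <- numeric(2 * n)
    for (o in seq_len(2 * n)) {
      src <- (o - 1) / 2 - 0.25
      f <- floor(src); fr <- src - f
      a <- min(max(f, 0), n - 1); b <- min(max(f + 1, 0), n - 1)
      i[o] <- o; j1[o] <- a + 1; j2[o] <- b + 1
      w1[o] <- 1 - fr; w2[o] <- fr
    }
    Matrix::sparseMatrix(i = c(i, i), j = c(j1, j2), x = c(w1, w2),
                         dims = c(2 * n, n))
  }
  U1 <- Matrix::kronecker(axis_mat(h), axis_mat(w))
  U <- Matrix::bdiag(rep(list(U1), B))
  U <- methods::as(U, "CsparseMatrix")
  .nn_cache[[key]] <- U
  U
}

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv3x3 <- function(cin, cout, bias = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv3x3"; ly$cin <- cin; ly$cout <- cout
  ly$W <- .he_init(9L * cin, cout, 9 * cin)
  ly$params <- "W"
  if (bias) { ly$b <- numeric(cout); ly$params <- c("W", "b") }
  ly
}

nn_dense <- function(cin, cout, bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dense"; ly$cin <- cin; ly$cout <- cout
  ly$W <- .he_init(cin, cout, cin)
  ly$params <- "W"
  if (bias) { ly$b <- numeric(cout); ly$params <- c("W", "b") }
  ly
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"; ly$c <- c
  ly$gamma <- rep(1, c); ly$beta <- numeric(c)
  ly$running_mean <- numeric(c); ly$running_var <- rep(1, c)
  ly$momentum <- momentum; ly$eps <- eps
  ly$params <- c("gamma", "beta")
  ly
}

nn_relu <- function() {
  ly <- new.env(parent = emptyenv())
  ly$type <- "relu"; ly$params <- character(0)
  ly
}

conv_forward <- function(ly, X, geom, train = TRUE) {
  Y <- .conv3x3_fwd_cpp(X, ly$W, geom$B, geom$H, geom$W)
  if (!is.null(ly$b)) Y <- Y + rep(ly$b, each = nrow(Y))
  if (train) ly$X <- X
  Y
}

conv_backward <- function(ly, dY, geom) {
  bw <- .conv3x3_bwd_cpp(ly$X, ly$W, dY, geom$B, geom$H, geom$W)
  ly$gW <- bw$dW
  if (!is.null(ly$b)) ly$gb <- colSums(dY)
  ly$X <- NULL
  bw$dX
}

dense_forward <- function(ly, X, train = TRUE) {
  Y <- X %*% ly$W
  if (!is.null(ly$b)) Y <- Y + rep(ly$b, each = nrow(Y))
  if (train) ly$X <- X
  Y
}

dense_backward <- function(ly, dY) {
  ly$gW <- crossprod(ly$X, dY)
  if (!is.null(ly$b)) ly$gb <- colSums(dY)
  dX <- tcrossprod(dY, ly$W)
  ly$X <- NULL
  dX
}

bn_forward <- function(ly, X, train = TRUE) {
  N <- nrow(X)
  if (train && N > 1) {
    fw <- .bn_fwd_cpp(X, ly$gamma, ly$beta, ly$eps)
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * as.vector(fw$mu)
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * as.vector(fw$var)
    ly$xhat <- fw$xhat; ly$var <- as.vector(fw$var); ly$batch_stats <- TRUE
    fw$y
  } else {
    invsd <- 1 / sqrt(ly$running_var + ly$eps)
    xhat <- (X - rep(ly$running_mean, each = N)) * rep(invsd, each = N)
    if (train) { ly$xhat <- xhat; ly$var <- ly$running_var; ly$batch_stats <- FALSE }
    xhat * rep(ly$gamma, each = N) + rep(ly$beta, each = N)
  }
}

bn_backward <- function(ly, dY) {
  if (isTRUE(ly$batch_stats)) {
    bw <- .bn_bwd_cpp(dY, ly$xhat, ly$gamma, ly$var, ly$eps)
    ly$ggamma <- as.vector(bw$ggamma); ly$gbeta <- as.vector(bw$gbeta)
    ly$xhat <- NULL
    bw$dX
  } else {
    # frozen-statistics fall-back (single-row batches): plain affine backprop
    N <- nrow(dY)
    ly$gbeta <- colSums(dY)
    ly$ggamma <- colSums(dY * ly$xhat)
    dX <- dY * rep(ly$gamma / sqrt(ly$var + ly$eps), each = N)
    ly$xhat <- NULL
    dX
  }
}

relu_forward <- function(ly, X, train = TRUE) {
  m <- X > 0
  if (train) ly$mask <- m
  X * m
}

relu_backward <- function(ly, dY) {
  out <- dY * ly$mask
  ly$mask <- NULL
  out
}

maxpool_forward <- function(st, X, geom, train = TRUE) {
  p <- geom$pidx
  if (is.null(p)) stop("maxpool needs even spatial dims")
  cur <- X[p[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (j in 2:4) {
    mj <- X[p[[j]], , drop = FALSE]
    sel <- mj > cur
    arg[sel] <- j
    cur[sel] <- mj[sel]
  }
  if (train) { st$arg <- arg; st$nin <- nrow(X) }
  cur
}

maxpool_backward <- function(st, dY, geom) {
  p <- geom$pidx
  dX <- matrix(0, st$nin, ncol(dY))
  for (j in 1:4) {
    dX[p[[j]], ] <- dY * (st$arg == j)
  }
  st$arg <- NULL
  dX
}

upsample_forward <- function(X, B, h, w) {
  U <- .get_upsample(B, h, w)
  as.matrix(U %*% X)
}

upsample_backward <- function(dY, B, h, w) {
  U <- .get_upsample(B, h, w)
  as.matrix(Matrix::crossprod(U, dY))
}

# Masked L1 loss. weight: 0/1 (or soft) per entry; returns mean over weights
# and the gradient wrt pred.
l1_loss <- function(pred, target, weight = NULL) {
  if (is.null(weight)) weight <- array(1, dim(pred) %||% length(pred))
  n <- sum(weight)
  if (n <= 0) stop("no supervised entries in loss (all weights zero)")
  d <- pred - target
  list(loss = sum(abs(d) * weight) / n,
       grad = sign(d) * weight / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- optimizers ------------------------------------------------------------

.grad_name <- function(p) paste0("g", p)

optimizer_state <- function(method = c("adam", "rmsprop"), lr0 = 1e-3,
                            weight_decay = 0) {
  method <- match.arg(method)
  st <- new.env(parent = emptyenv())
  st$method <- method; st$lr0 <- lr0; st$wd <- weight_decay; st$t <- 0L
  st
}

optimizer_step <- function(st, layers, lr) {
  st$t <- st$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; alpha <- 0.99
  for (ly in layers) {
    for (p in ly$params) {
      g <- ly[[.grad_name(p)]]
      if (is.null(g)) next
      if (st$wd > 0) g <- g + st$wd * ly[[p]]
      if (st$method == "adam") {
        mk <- paste0(".m_", p); vk <- paste0(".v_", p)
        if (is.null(ly[[mk]])) { ly[[mk]] <- g * 0; ly[[vk]] <- g * 0 }
        ly[[mk]] <- b1 * ly[[mk]] + (1 - b1) * g
        ly[[vk]] <- b2 * ly[[vk]] + (1 - b2) * g * g
        mhat <- ly[[mk]] / (1 - b1^st$t)
        vhat <- ly[[vk]] / (1 - b2^st$t)
        ly[[p]] <- ly[[p]] - lr * mhat / (sqrt(vhat) + eps)
      } else {
        vk <- paste0(".v_", p)
        if (is.null(ly[[vk]])) ly[[vk]] <- g * 0
        ly[[vk]] <- alpha * ly[[vk]] + (1 - alpha) * g * g
        ly[[p]] <- ly[[p]] - lr * g / (sqrt(ly[[vk]]) + eps)
      }
      ly[[.grad_name(p)]] <- NULL
    }
  }
  invisible(st)
}
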