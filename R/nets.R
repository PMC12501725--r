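#' Output-range limiter configuration
#'
#' The limiter head clamps regressor outputs to a physiologically plausible
#' T1rho range: `y = min(ReLU(x) + ymin, ymax)`. Defaults 10 and 100 ms.
#'
#' @param ymin,ymax Lower and upper bound in ms, `0 < ymin < ymax`.
#' @return An object of class `limiter_config`.
#' @export
limiter_config <- function(ymin = 10, ymax = 100) {
  if (!(is.numeric(ymin) && is.numeric(ymax) && ymin > 0 && ymax > ymin))
    stop("need 0 < ymin < ymax")
  structure(list(ymin = ymin, ymax = ymax), class = "limiter_config")
}

#' Apply the prediction-range limiter
#'
#' `y = min(ReLU(x) + ymin, ymax)`: negative regressor activations map to
#' `ymin`, arbitrarily large ones to `ymax`, so every prediction lies in
#' `[ymin, ymax]`. Mispredictions outside the range receive zero gradient
#' during training, which constrains the optimization to the plausible range.
#'
#' @param x Regressor output(s); must be finite.
#' @param cfg A [limiter_config()].
#' @return Limited value(s) in ms, same shape as `x`.
#' @examples
#' apply_limiter(c(-3, 42, 1e6), limiter_config())  # 10, 52, 100
#' @export
apply_limiter <- function(x, cfg = limiter_config()) {
  if (any(!is.finite(x))) stop("'x' must be finite")
  pmin(pmax(x, 0) + cfg$ymin, cfg$ymax)
}

# limiter gradient mask wrt x
.limiter_mask <- function(x, cfg) (x > 0) & ((x + cfg$ymin) < cfg$ymax)

#' 2D U-Net configuration
#'
#' @param depth Number of pooling levels in the encoder.
#' @param base_channels Channels of the first encoder level; doubled per level.
#' @param in_channels Input channels (the I0-like and Ik-like contrast pair).
#' @param patch_size Square patch edge in pixels; must be divisible by
#'   `2^depth`.
#' @param limiter A [limiter_config()].
#' @param seed Seed for the deterministic weight initialization.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4, base_channels = 32, in_channels = 2,
                        patch_size = 64, limiter = limiter_config(),
                        seed = 1L) {
  stopifnot(depth >= 1, base_channels >= 1)
  if (in_channels != 2) stop("the predictor takes exactly 2 input channels")
  if (patch_size %% 2^depth != 0)
    stop("'patch_size' must be divisible by 2^depth")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = 2L, patch_size = as.integer(patch_size),
                 limiter = limiter, seed = as.integer(seed)),
            class = "unet_config")
}

#' Build the 2D U-Net regressor
#'
#' A standard encoder-decoder with two 3x3 conv + batch-norm + ReLU blocks per
#' level, 2x2 max pooling, bilinear upsampling with skip concatenation, a 1x1
#' convolution regressor head and the output-range limiter. Maps a 2-channel
#' patch to a single-channel T1rho patch of identical spatial size with every
#' value in `[ymin, ymax]`. Weight initialization is deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [unet_config()].
#' @return A model object of class `t1rho_unet`.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  set.seed(cfg$seed)
  d <- cfg$depth; ch <- cfg$base_channels * 2^(0:d)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  blk <- function(cin, cmid) list(conv1 = nn_conv3x3(cin, cmid),
                                  bn1 = nn_bn(cmid), relu1 = nn_relu(),
                                  conv2 = nn_conv3x3(cmid, cmid),
                                  bn2 = nn_bn(cmid), relu2 = nn_relu())
  m$enc <- vector("list", d)
  cin <- cfg$in_channels
  for (i in seq_len(d)) {
    m$enc[[i]] <- blk(cin, ch[i])
    cin <- ch[i]
  }
  m$pool <- lapply(seq_len(d), function(i) new.env(parent = emptyenv()))
  m$bott <- blk(ch[d], ch[d + 1])
  m$dec <- vector("list", d)
  for (i in d:1) m$dec[[i]] <- blk(ch[i] + ch[i + 1], ch[i])
  m$head <- nn_dense(ch[1], 1L, bias = TRUE)   # 1x1 convolution
  # start the regressor mid-range of the limiter: a zero bias would leave the
  # ReLU side of the limiter saturated at init, blocking all gradients
  m$head$b <- (cfg$limiter$ymin + cfg$limiter$ymax) / 2 - cfg$limiter$ymin
  m$layers <- c(unlist(lapply(m$enc, function(b) b[c("conv1", "bn1", "conv2", "bn2")]),
                       use.names = FALSE),
                m$bott[c("conv1", "bn1", "conv2", "bn2")],
                unlist(lapply(m$dec, function(b) b[c("conv1", "bn1", "conv2", "bn2")]),
                       use.names = FALSE),
                list(m$head))
  class(m) <- "t1rho_unet"
  m
}

.unet_block_fwd <- function(b, X, geom, train) {
  X <- relu_forward(b$relu1, bn_forward(b$bn1, conv_forward(b$conv1, X, geom, train), train), train)
  relu_forward(b$relu2, bn_forward(b$bn2, conv_forward(b$conv2, X, geom, train), train), train)
}

.unet_block_bwd <- function(b, dY, geom) {
  dY <- conv_backward(b$conv2, bn_backward(b$bn2, relu_backward(b$relu2, dY)), geom)
  conv_backward(b$conv1, bn_backward(b$bn1, relu_backward(b$relu1, dY)), geom)
}

# Forward pass. x: (B, 2, H, W) array. Returns (B, H, W) array of limited
# T1rho predictions; caches for backward when train = TRUE.
unet_forward <- function(m, x, train = FALSE) {
  d <- m$cfg$depth
  dims <- dim(x); B <- dims[1]; H <- dims[3]; W <- dims[4]
  if (H %% 2^d != 0 || W %% 2^d != 0)
    stop("spatial dims must be divisible by 2^depth")
  X <- .arr_to_mat(x)
  hs <- H; ws <- W
  skips <- vector("list", d); sizes <- matrix(0L, d + 1, 2)
  for (i in seq_len(d)) {
    g <- .get_geom(B, hs, ws)
    X <- .unet_block_fwd(m$enc[[i]], X, g, train)
    skips[[i]] <- X
    sizes[i, ] <- c(hs, ws)
    X <- maxpool_forward(m$pool[[i]], X, g, train)
    hs <- hs %/% 2L; ws <- ws %/% 2L
  }
  sizes[d + 1, ] <- c(hs, ws)
  X <- .unet_block_fwd(m$bott, X, .get_geom(B, hs, ws), train)
  for (i in d:1) {
    X <- upsample_forward(X, B, sizes[i + 1, 1], sizes[i + 1, 2])
    X <- cbind(skips[[i]], X)
    X <- .unet_block_fwd(m$dec[[i]], X, .get_geom(B, sizes[i, 1], sizes[i, 2]), train)
  }
  Xr <- dense_forward(m$head, X, train)
  y <- apply_limiter(Xr, m$cfg$limiter)
  if (train) {
    m$fw <- list(B = B, H = H, W = W, sizes = sizes,
                 lim_mask = .limiter_mask(Xr, m$cfg$limiter))
  }
  aperm(array(y, c(W, H, B)), c(3, 2, 1))
}

# Backward pass from d loss / d prediction, a (B, H, W) array. The forward
# decoder ran levels d..1, so the backward walks dec 1..d down to the
# bottleneck, then back up the encoder adding the skip gradients.
unet_backward <- function(m, dy) {
  fw <- m$fw; d <- m$cfg$depth
  B <- fw$B; H <- fw$H; W <- fw$W
  dY <- .arr_to_mat(array(dy, c(B, 1, H, W)))
  dY <- dY * fw$lim_mask
  dY <- dense_backward(m$head, dY)
  dskips <- vector("list", d)
  for (i in 1:d) {                       # forward ran dec d..1, backward 1..d
    g <- .get_geom(B, fw$sizes[i, 1], fw$sizes[i, 2])
    dY <- .unet_block_bwd(m$dec[[i]], dY, g)
    csk <- m$cfg$base_channels * 2^(i - 1)
    dskips[[i]] <- dY[, seq_len(csk), drop = FALSE]
    dup <- dY[, -seq_len(csk), drop = FALSE]
    dY <- upsample_backward(dup, B, fw$sizes[i + 1, 1], fw$sizes[i + 1, 2])
  }
  dY <- .unet_block_bwd(m$bott, dY, .get_geom(B, fw$sizes[d + 1, 1], fw$sizes[d + 1, 2]))
  for (i in d:1) {
    g <- .get_geom(B, fw$sizes[i, 1], fw$sizes[i, 2])
    dY <- maxpool_backward(m$pool[[i]], dY, g) + dskips[[i]]
    dY <- .unet_block_bwd(m$enc[[i]], dY, g)
  }
  m$fw <- NULL
  invisible(dY)
}

#' 1D MLP configuration
#'
#' @param n_blocks Number of FC-ReLU-BN blocks.
#' @param width Units per block.
#' @param in_features Input features (the I0-like and Ik-like intensities).
#' @param skip Enable residual connections between blocks of equal width.
#' @param limiter A [limiter_config()] applied to the output, or `NULL` for an
#'   unconstrained regressor.
#' @param seed Seed for the deterministic weight initialization.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(n_blocks = 4, width = 64, in_features = 2,
                       skip = TRUE, limiter = limiter_config(), seed = 1L) {
  stopifnot(n_blocks >= 1, width >= 1)
  if (in_features != 2) stop("the predictor takes exactly 2 input features")
  if (!is.null(limiter)) stopifnot(inherits(limiter, "limiter_config"))
  structure(list(n_blocks = as.integer(n_blocks), width = as.integer(width),
                 in_features = 2L, skip = isTRUE(skip), limiter = limiter,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Build the 1D MLP predictor
#'
#' Maps rows of `(I0-like, Ik-like)` voxel intensities to one T1rho value per
#' row through `n_blocks` FC-ReLU-BN blocks with residual connections between
#' equal-width blocks, a final linear unit and (optionally) the range limiter.
#'
#' @param cfg An [mlp_config()].
#' @return A model object of class `t1rho_mlp`.
#' @export
build_mlp <- function(cfg) {
  stopifnot(inherits(cfg, "mlp_config"))
  set.seed(cfg$seed)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$blocks <- vector("list", cfg$n_blocks)
  cin <- cfg$in_features
  for (i in seq_len(cfg$n_blocks)) {
    m$blocks[[i]] <- list(fc = nn_dense(cin, cfg$width), relu = nn_relu(),
                          bn = nn_bn(cfg$width), skip_in = cin == cfg$width)
    cin <- cfg$width
  }
  m$head <- nn_dense(cfg$width, 1L)
  # start mid-range (see build_unet): keeps the limiter unsaturated at init
  m$head$b <- if (!is.null(cfg$limiter))
    (cfg$limiter$ymin + cfg$limiter$ymax) / 2 - cfg$limiter$ymin else 50
  m$layers <- c(unlist(lapply(m$blocks, function(b) b[c("fc", "bn")]),
                       use.names = FALSE),
                list(m$head))
  class(m) <- "t1rho_mlp"
  m
}

# x: n x 2 matrix -> n predictions.
mlp_forward <- function(m, x, train = FALSE) {
  X <- as.matrix(x)
  for (b in m$blocks) {
    U <- bn_forward(b$bn, relu_forward(b$relu, dense_forward(b$fc, X, train), train), train)
    X <- if (m$cfg$skip && b$skip_in) U + X else U
  }
  Xr <- dense_forward(m$head, X, train)
  if (!is.null(m$cfg$limiter)) {
    if (train) m$lim_mask <- .limiter_mask(Xr, m$cfg$limiter)
    Xr <- apply_limiter(Xr, m$cfg$limiter)
  }
  as.vector(Xr)
}

mlp_backward <- function(m, dy) {
  dY <- matrix(dy, ncol = 1)
  if (!is.null(m$cfg$limiter)) { dY <- dY * m$lim_mask; m$lim_mask <- NULL }
  dY <- dense_backward(m$head, dY)
  for (i in rev(seq_along(m$blocks))) {
    b <- m$blocks[[i]]
    dU <- bn_backward(b$bn, dY)
    dX <- dense_backward(b$fc, relu_backward(b$relu, dU))
    dY <- if (m$cfg$skip && b$skip_in) dX + dY else dX
  }
  invisible(dY)
}

#' @export
print.t1rho_unet <- function(x, ...) {
  cat(sprintf("t1rho_unet: depth %d, base %d channels, patch %d, limiter [%g, %g] ms\n",
              x$cfg$depth, x$cfg$base_channels, x$cfg$patch_size,
              x$cfg$limiter$ymin, x$cfg$limiter$ymax))
  invisible(x)
}

#' @export
print.t1rho_mlp <- function(x, ...) {
  cat(sprintf("t1rho_mlp: %d FC-ReLU-BN blocks of width %d%s%s\n",
              x$cfg$n_blocks, x$cfg$width,
              if (x$cfg$skip) ", residual skips" else "",
              if (!is.null(x$cfg$limiter))
                sprintf(", limiter [%g, %g] ms", x$cfg$limiter$ymin, x$cfg$limiter$ymax)
              else ""))
  invisible(x)
}

# --- checkpoints -----------------------------------------------------------

.model_state <- function(m) {
  lapply(m$layers, function(ly) {
    s <- lapply(ly$params, function(p) ly[[p]])
    names(s) <- ly$params
    if (ly$type == "bn") {
      s$running_mean <- ly$running_mean
      s$running_var <- ly$running_var
    }
    s
  })
}

.restore_state <- function(m, state) {
  stopifnot(length(state) == length(m$layers))
  for (i in seq_along(state)) {
    ly <- m$layers[[i]]
    for (nm in names(state[[i]])) ly[[nm]] <- state[[i]][[nm]]
  }
  invisible(m)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a self-describing list: the model kind, its full config
#' and all parameters and batch-norm statistics.
#'
#' @param model A `t1rho_unet` or `t1rho_mlp`.
#' @param path File path for the checkpoint.
#' @return `load_model` returns the rebuilt model.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "t1rho_unet")) "unet" else if
    (inherits(model, "t1rho_mlp")) "mlp" else stop("unknown model type")
  saveRDS(list(kind = kind, cfg = model$cfg, state = .model_state(model),
               package = "t1rhomap"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  m <- switch(ck$kind, unet = build_unet(ck$cfg), mlp = build_mlp(ck$cfg),
              stop("unknown checkpoint kind"))
  .restore_state(m, ck$state)
}
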