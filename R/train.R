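#' Augmentation configuration
#'
#' Geometric transforms are applied with identical geometry to the input
#' channels and the target; Gaussian noise is added to the input channels
#' only. All-zero settings give the identity.
#'
#' @param flip Probability of a flip along each in-plane axis.
#' @param rotation Maximum rotation magnitude (degrees, drawn uniformly).
#' @param translation Maximum in-plane translation (pixels, drawn uniformly).
#' @param gaussian_noise_sigma Noise standard deviation as a fraction of the
#'   normalized intensity scale (inputs are pre-scaled to ~1).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(flip = 0.5, rotation = 15, translation = 8,
                           gaussian_noise_sigma = 0.02) {
  stopifnot(flip >= 0, flip <= 1, rotation >= 0, translation >= 0,
            gaussian_noise_sigma >= 0)
  structure(list(flip = flip, rotation = rotation, translation = translation,
                 gaussian_noise_sigma = gaussian_noise_sigma),
            class = "augment_config")
}

#' Training configuration
#'
#' Defaults follow the published recipes: L1 loss; U-Net trained with Adam
#' (initial learning rate 1e-3, exponential decay 0.9 per epoch, weight decay
#' 3e-4); MLP with RMSProp (same learning-rate schedule and weight decay) and
#' batch size 512; 64-pixel patches cropped with a higher probability around
#' the cartilage ROI.
#'
#' @param optimizer `"adam"` (U-Net recipe) or `"rmsprop"` (MLP recipe).
#' @param lr0 Initial learning rate.
#' @param lr_decay Exponential decay factor applied per epoch:
#'   `lr(e) = lr0 * lr_decay^(e-1)`.
#' @param weight_decay L2 weight decay added to the gradients.
#' @param epochs Number of training epochs.
#' @param batch_size Patches (U-Net) or voxel rows (MLP) per batch.
#' @param patch_size Square patch edge for the U-Net.
#' @param roi_bias Probability that a patch center is drawn from ROI voxels.
#' @param patches_per_slice Patches sampled per ROI-containing slice per epoch.
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @param masked_inputs Zero input voxels outside the ROI before training and
#'   inference.
#' @param roi_loss_only Compute the loss (and gradients) only over ROI voxels.
#' @param seed Seed controlling patch sampling, augmentation and batching.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "rmsprop"), lr0 = 1e-3,
                         lr_decay = 0.9, weight_decay = 3e-4, epochs = 1000,
                         batch_size = 16, patch_size = 64, roi_bias = 0.8,
                         patches_per_slice = 4, augment = augment_config(),
                         masked_inputs = FALSE, roi_loss_only = FALSE,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr_decay > 0, lr_decay <= 1, epochs >= 1, batch_size >= 1,
            roi_bias >= 0, roi_bias <= 1, patches_per_slice >= 1)
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_config"))
  structure(list(loss = "L1", optimizer = optimizer, lr0 = lr0,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), roi_bias = roi_bias,
                 patches_per_slice = as.integer(patches_per_slice),
                 augment = augment, masked_inputs = isTRUE(masked_inputs),
                 roi_loss_only = isTRUE(roi_loss_only), seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified k-fold split
#'
#' Subjects are shuffled within each stratum and dealt round-robin into folds
#' (the deal position carries across strata), so folds are mutually exclusive,
#' jointly exhaustive, of size within one of each other, and each stratum is
#' spread across folds within one subject of proportional.
#'
#' @param subject_ids Character or integer vector of unique subject ids.
#' @param strata Stratum label per subject (same length).
#' @param k Number of folds, `2 <= k <= length(subject_ids)`.
#' @param seed Shuffle seed.
#' @return An object of class `fold_split`: list with `assignments` (named
#'   integer vector of fold indices 1..k), `k` and `strata`.
#' @export
make_folds <- function(subject_ids, strata, k, seed = 1L) {
  if (k < 2) stop("'k' must be at least 2")
  n <- length(subject_ids)
  if (k > n) stop("more folds than subjects")
  if (length(strata) != n) stop("'strata' must match 'subject_ids'")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  set.seed(as.integer(seed))
  assignments <- integer(n); names(assignments) <- as.character(subject_ids)
  pos <- 0L
  for (s in sort(unique(as.character(strata)))) {
    members <- which(as.character(strata) == s)
    members <- members[sample.int(length(members))]
    for (m in members) {
      assignments[m] <- (pos %% k) + 1L
      pos <- pos + 1L
    }
  }
  structure(list(assignments = assignments, k = as.integer(k),
                 strata = stats::setNames(as.character(strata),
                                          as.character(subject_ids))),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: %d subjects in %d folds (sizes %s)\n",
              length(x$assignments), x$k,
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

# bilinear sampling of a matrix at fractional coordinates; zero outside
.bilinear_sample <- function(img, rs, cs) .bilinear_cpp(img, rs, cs)

.nearest_sample <- function(img, rs, cs) {
  H <- nrow(img); W <- ncol(img)
  r <- round(rs); c <- round(cs)
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  out <- numeric(length(r))
  out[ok] <- img[cbind(r[ok], c[ok])]
  matrix(out, H, W)
}

#' Augment one training patch
#'
#' Random flips are exact index reversals; rotation and translation are a
#' single affine resampling (bilinear for intensities and target, nearest for
#' the ROI patch); Gaussian noise goes to the input channels only. An all-zero
#' [augment_config()] returns the inputs unchanged.
#'
#' @param input 3D array (channels, h, w).
#' @param target Matrix (h, w); transformed with the same geometry.
#' @param cfg An [augment_config()].
#' @param seed Optional seed; `NULL` draws from the ambient RNG stream.
#' @param roi Optional ROI patch (h, w), transformed with nearest-neighbor
#'   sampling.
#' @return List with `input`, `target` and (if given) `roi`.
#' @export
augment_patch <- function(input, target, cfg, seed = NULL, roi = NULL) {
  stopifnot(length(dim(input)) == 3, identical(dim(input)[2:3], dim(target)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  h <- dim(input)[2]; w <- dim(input)[3]
  if (cfg$flip > 0) {
    if (stats::runif(1) < cfg$flip) {     # vertical (row) flip
      input <- input[, h:1, , drop = FALSE]
      target <- target[h:1, , drop = FALSE]
      if (!is.null(roi)) roi <- roi[h:1, , drop = FALSE]
    }
    if (stats::runif(1) < cfg$flip) {     # horizontal (col) flip
      input <- input[, , w:1, drop = FALSE]
      target <- target[, w:1, drop = FALSE]
      if (!is.null(roi)) roi <- roi[, w:1, drop = FALSE]
    }
  }
  ang <- if (cfg$rotation > 0) stats::runif(1, -cfg$rotation, cfg$rotation) else 0
  tr <- if (cfg$translation > 0) stats::runif(2, -cfg$translation, cfg$translation) else c(0, 0)
  if (ang != 0 || any(tr != 0)) {
    th <- ang * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    dr <- matrix(seq_len(h), h, w) - cy
    dc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    rs <- cos(th) * dr - sin(th) * dc + cy - tr[1]
    cs <- sin(th) * dr + cos(th) * dc + cx - tr[2]
    for (ch in seq_len(dim(input)[1]))
      input[ch, , ] <- .bilinear_sample(input[ch, , ], rs, cs)
    target <- .bilinear_sample(target, rs, cs)
    if (!is.null(roi)) roi <- .nearest_sample(roi, rs, cs)
  }
  if (cfg$gaussian_noise_sigma > 0) {
    input <- input + array(stats::rnorm(length(input), 0, cfg$gaussian_noise_sigma),
                           dim(input))
  }
  out <- list(input = input, target = target)
  if (!is.null(roi)) out$roi <- roi
  out
}

# one patch draw: top-left corner given an ROI-biased center
.draw_patch_corner <- function(H, W, ps, roi_slice, roi_bias) {
  use_roi <- !is.null(roi_slice) && any(roi_slice > 0) &&
    stats::runif(1) < roi_bias
  if (use_roi) {
    pos <- which(roi_slice > 0)
    p <- pos[sample.int(length(pos), 1L)]
    r <- (p - 1L) %% H + 1L          # column-major index of matrix
    c <- (p - 1L) %/% H + 1L
  } else {
    r <- sample.int(H, 1L); c <- sample.int(W, 1L)
  }
  c(min(max(r - ps %/% 2L, 1L), H - ps + 1L),
    min(max(c - ps %/% 2L, 1L), W - ps + 1L))
}

#' Sample training patches from one slice
#'
#' Crops `n` square patches; with probability `cfg$roi_bias` a patch is
#' centered on a uniformly drawn ROI voxel of the slice, otherwise uniformly
#' on the slice. Patch corners are clamped so every patch lies inside the
#' slice.
#'
#' @param slice_pair 3D array (2, H, W): the two input channels.
#' @param target Matrix (H, W) of target T1rho values.
#' @param roi_slice Matrix (H, W) of ROI labels.
#' @param n Number of patches.
#' @param cfg A [train_config()] (uses `patch_size` and `roi_bias`).
#' @param seed Optional seed; `NULL` draws from the ambient RNG stream.
#' @return List of `n` lists with elements `input` (2, ps, ps), `target`
#'   (ps, ps) and `roi` (ps, ps).
#' @export
sample_patches <- function(slice_pair, target, roi_slice, n, cfg, seed = NULL) {
  ps <- cfg$patch_size
  H <- dim(slice_pair)[2]; W <- dim(slice_pair)[3]
  if (H < ps || W < ps) stop("slice smaller than the patch size")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    tl <- .draw_patch_corner(H, W, ps, roi_slice, cfg$roi_bias)
    rr <- tl[1]:(tl[1] + ps - 1L); cc <- tl[2]:(tl[2] + ps - 1L)
    list(input = slice_pair[, rr, cc, drop = FALSE],
         target = target[rr, cc], roi = roi_slice[rr, cc],
         corner = tl)
  })
}

#' Zero all voxels outside the ROI
#'
#' @param volumes A [weighted_volume()] or list thereof (bare arrays also
#'   accepted).
#' @param roi A [roi_mask()] of matching shape.
#' @return Same structure with non-ROI voxels set to exactly 0.
#' @export
mask_to_roi <- function(volumes, roi) {
  lab <- roi_labels(roi)
  one <- function(v) {
    arr <- if (inherits(v, "weighted_volume")) v$data else v
    if (!identical(dim(arr), dim(lab))) stop("shape mismatch between volume and ROI")
    arr[lab == 0] <- 0
    if (inherits(v, "weighted_volume")) { v$data <- arr; v } else arr
  }
  if (inherits(volumes, "weighted_volume") || is.array(volumes)) one(volumes)
  else lapply(volumes, one)
}

# Subject-level intensity normalization: mean I0 intensity inside the ROI's
# bounding box. Keeps the I0/Ik ratio meaningful while stabilizing the
# arbitrary scanner units.
.norm_scale <- function(i0_arr, roi_lab) {
  idx <- which(roi_lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mean(i0_arr[i0_arr > 0]))
  rng <- apply(idx, 2, range)
  box <- i0_arr[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3]]
  mean(box)
}

# Resolve an I0/Ik combination against a phantom subject.
.combo_volumes <- function(subject, combo) {
  stopifnot(is.list(combo), combo$i0 %in% c("pd", "tsl0"), is.numeric(combo$ik))
  tsls <- vapply(subject$volumes, function(v) v$tsl, 0)
  vi0 <- if (combo$i0 == "pd") subject$pd_volume else {
    j <- which(tsls == 0)
    if (!length(j)) stop("subject has no TSL = 0 volume")
    subject$volumes[[j[1]]]
  }
  j <- which(tsls == combo$ik)
  if (!length(j)) stop(sprintf("subject has no TSL = %g ms volume", combo$ik))
  list(i0 = vi0, ik = subject$volumes[[j[1]]])
}

#' Assemble a per-subject training set for one input combination
#'
#' Selects the I0-like and Ik-like volumes, normalizes both channels by the
#' subject-level mean I0 intensity inside the ROI bounding box, optionally
#' zeroes non-ROI input voxels, and attaches the ground-truth map.
#'
#' @param subjects List of `phantom_subject`s (or compatible lists).
#' @param truth_maps Named list of `t1rho_map`s keyed by subject id.
#' @param combo List with `i0` (`"pd"` or `"tsl0"`) and `ik` (TSL in ms).
#' @param masked_inputs Zero non-ROI input voxels.
#' @return List of per-subject entries used by the trainers and predictors.
#' @export
make_training_set <- function(subjects, truth_maps, combo,
                              masked_inputs = FALSE) {
  lapply(subjects, function(sub) {
    vols <- .combo_volumes(sub, combo)
    lab <- roi_labels(sub$roi)
    scale <- .norm_scale(vols$i0$data, lab)
    x1 <- vols$i0$data / scale
    x2 <- vols$ik$data / scale
    if (masked_inputs) { x1[lab == 0] <- 0; x2[lab == 0] <- 0 }
    tm <- truth_maps[[sub$id]]
    stopifnot(inherits(tm, "t1rho_map"))
    slices <- which(apply(lab > 0, 1, any))
    list(id = sub$id, x1 = x1, x2 = x2, roi = lab,
         target = tm$values, valid = tm$valid, slices = slices)
  })
}

.lr_at <- function(cfg, epoch) cfg$lr0 * cfg$lr_decay^(epoch - 1)

#' Train the 2D U-Net
#'
#' ROI-biased 64x64 patches are cropped from every ROI-containing slice each
#' epoch, augmented, and fed in mini-batches; the L1 loss against the
#' ground-truth T1rho patch is taken over all valid target voxels, or only
#' over ROI voxels when `cfg$roi_loss_only` is set. The learning rate decays
#' exponentially per epoch. Deterministic for fixed seeds (single-threaded).
#'
#' @param dataset Output of [make_training_set()]; must be non-empty.
#' @param cfg A [train_config()] (typically `optimizer = "adam"`).
#' @param unet_cfg A [unet_config()].
#' @return List with `model` (a `t1rho_unet`) and `history` (per-epoch mean
#'   loss).
#' @export
train_unet <- function(dataset, cfg, unet_cfg) {
  if (length(dataset) == 0) stop("empty training set")
  stopifnot(inherits(cfg, "train_config"), inherits(unet_cfg, "unet_config"))
  if (cfg$roi_loss_only && !any(vapply(dataset, function(d) any(d$roi > 0), TRUE)))
    stop("roi_loss_only = TRUE but the ROI masks contain no voxels")
  model <- build_unet(unet_cfg)
  opt <- optimizer_state(cfg$optimizer, cfg$lr0, cfg$weight_decay)
  set.seed(cfg$seed)
  pairs <- do.call(rbind, lapply(seq_along(dataset), function(i) {
    sl <- dataset[[i]]$slices
    if (!length(sl)) return(NULL)
    cbind(i, sl)
  }))
  if (is.null(pairs)) stop("no ROI-containing slices in the training set")
  ps <- cfg$patch_size
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- .lr_at(cfg, epoch)
    patches <- list()
    for (j in seq_len(nrow(pairs))) {
      d <- dataset[[pairs[j, 1]]]; s <- pairs[j, 2]
      sp <- array(0, c(2, dim(d$x1)[2], dim(d$x1)[3]))
      sp[1, , ] <- d$x1[s, , ]; sp[2, , ] <- d$x2[s, , ]
      wt_slice <- if (cfg$roi_loss_only) (d$roi[s, , ] > 0) * 1 else d$valid[s, , ] * 1
      tgt_slice <- d$target[s, , ]
      # unsupervised voxels carry no target; zeroing them keeps the loss
      # independent of their content even under interpolating augmentation
      tgt_slice[wt_slice == 0] <- 0
      drawn <- sample_patches(sp, tgt_slice, d$roi[s, , ],
                              cfg$patches_per_slice, cfg)
      for (p in drawn) {
        rr <- p$corner[1]:(p$corner[1] + ps - 1L)
        cc <- p$corner[2]:(p$corner[2] + ps - 1L)
        p$weight <- wt_slice[rr, cc]
        if (!is.null(cfg$augment)) {
          # the loss-weight mask rides along in the (nearest-sampled) roi slot
          a <- augment_patch(p$input, p$target, cfg$augment, roi = p$weight)
          p$input <- a$input; p$target <- a$target; p$weight <- a$roi
        }
        patches[[length(patches) + 1L]] <- p
      }
    }
    ord <- sample.int(length(patches))
    losses <- c()
    for (b in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[b:min(b + cfg$batch_size - 1L, length(ord))]
      B <- length(idx)
      xb <- array(0, c(B, 2, ps, ps)); tb <- array(0, c(B, ps, ps))
      wb <- array(0, c(B, ps, ps))
      for (q in seq_len(B)) {
        p <- patches[[idx[q]]]
        xb[q, , , ] <- p$input; tb[q, , ] <- p$target; wb[q, , ] <- p$weight
      }
      if (sum(wb) == 0) next
      pred <- unet_forward(model, xb, train = TRUE)
      ls <- l1_loss(pred, tb, wb)
      unet_backward(model, ls$grad)
      optimizer_step(opt, model$layers, lr)
      losses <- c(losses, ls$loss)
    }
    history[epoch] <- if (length(losses)) mean(losses) else NA_real_
  }
  list(model = model, history = history)
}

#' Train the 1D MLP
#'
#' Voxel intensity pairs are extracted from the cartilage ROI only, shuffled
#' every epoch and fed in full batches of `cfg$batch_size` rows (a trailing
#' partial batch is dropped) with L1 loss against the ground-truth T1rho of
#' each voxel.
#'
#' @param dataset Output of [make_training_set()].
#' @param cfg A [train_config()] (typically `optimizer = "rmsprop"`,
#'   `batch_size = 512`).
#' @param mlp_cfg An [mlp_config()].
#' @return List with `model` (a `t1rho_mlp`) and `history` (per-epoch mean
#'   loss).
#' @export
train_mlp <- function(dataset, cfg, mlp_cfg) {
  if (length(dataset) == 0) stop("empty training set")
  stopifnot(inherits(cfg, "train_config"), inherits(mlp_cfg, "mlp_config"))
  X <- do.call(rbind, lapply(dataset, function(d) {
    sel <- d$roi > 0 & d$valid
    cbind(d$x1[sel], d$x2[sel], d$target[sel])
  }))
  if (is.null(X) || nrow(X) == 0) stop("no ROI voxels available for training")
  model <- build_mlp(mlp_cfg)
  opt <- optimizer_state(cfg$optimizer, cfg$lr0, cfg$weight_decay)
  set.seed(cfg$seed)
  n <- nrow(X)
  history <- numeric(cfg$epochs)
  nb <- n %/% cfg$batch_size
  if (nb == 0) nb <- 1  # tiny datasets: one (partial) batch
  for (epoch in seq_len(cfg$epochs)) {
    lr <- .lr_at(cfg, epoch)
    ord <- sample.int(n)
    losses <- numeric(nb)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n)]
      xb <- X[idx, 1:2, drop = FALSE]
      yb <- X[idx, 3]
      pred <- mlp_forward(model, xb, train = TRUE)
      ls <- l1_loss(pred, yb)
      mlp_backward(model, ls$grad)
      optimizer_step(opt, model$layers, lr)
      losses[b] <- ls$loss
    }
    history[epoch] <- mean(losses)
  }
  attr(history, "n_batches") <- nb
  attr(history, "batch_size") <- min(cfg$batch_size, n)
  list(model = model, history = history)
}

# The six published I0/Ik combinations.
.valid_combos <- function() {
  out <- expand.grid(i0 = c("pd", "tsl0"), ik = c(10, 30, 50),
                     stringsAsFactors = FALSE)
  out[order(out$i0, out$ik), ]
}

.check_combo <- function(combo, learner = TRUE) {
  ok <- .valid_combos()
  if (!any(ok$i0 == combo$i0 & ok$ik == combo$ik)) {
    if (learner || !(combo$i0 %in% c("pd", "tsl0")))
      stop(sprintf(
        "combo (%s, TSL %s ms) is not a valid I0/Ik combination; legal: %s",
        combo$i0, combo$ik,
        paste(sprintf("(%s, %g)", ok$i0, ok$ik), collapse = " ")))
  }
  invisible(TRUE)
}

#' Cross-validated training, prediction and evaluation
#'
#' Trains one model per fold on the complementary folds and predicts each
#' subject exactly once, with the model that never saw it; per-subject metrics
#' are computed against the ground-truth maps over the unified cartilage ROI
#' and aggregated into a cohort summary.
#'
#' @param cohort List of `phantom_subject`s.
#' @param folds A [make_folds()] split over the cohort ids.
#' @param model `"mlp"`, `"unet"` or `"nlls"` (the latter skips training and
#'   fits the two selected volumes directly).
#' @param combo List with `i0` in `"pd"`/`"tsl0"` and `ik` in 10/30/50 (ms).
#' @param train_cfg A [train_config()] (ignored for `"nlls"`).
#' @param net_cfg A [unet_config()] or [mlp_config()] matching `model`.
#' @param truth_maps Optional named list of ground-truth `t1rho_map`s; by
#'   default the 4-point NLLS fit of each subject's full TSL series.
#' @param stride Sliding-window stride for U-Net inference.
#' @return List with `predictions` (named list of `t1rho_map`), `metrics`
#'   (per-subject `data.frame` with fold bookkeeping), `summary` (cohort
#'   mean/sd per metric), `folds`, and `truth_maps`.
#' @export
run_cross_validation <- function(cohort, folds, model = c("mlp", "unet", "nlls"),
                                 combo = list(i0 = "tsl0", ik = 50),
                                 train_cfg = NULL, net_cfg = NULL,
                                 truth_maps = NULL, stride = 32L) {
  model <- match.arg(model)
  .check_combo(combo, learner = model != "nlls")
  ids <- vapply(cohort, function(s) s$id, "")
  stopifnot(setequal(ids, names(folds$assignments)))
  if (is.null(truth_maps)) {
    truth_maps <- lapply(cohort, function(sub)
      fit_volume(sub$volumes, sub$protocol, roi = NULL, method = "nlls"))
    names(truth_maps) <- ids
  }
  predictions <- vector("list", length(cohort)); names(predictions) <- ids
  trained_without <- character(0)
  rows <- list()
  for (f in seq_len(folds$k)) {
    test_ids <- names(folds$assignments)[folds$assignments == f]
    train_ids <- setdiff(ids, test_ids)
    fitted <- NULL
    if (model != "nlls") {
      tc <- train_cfg
      tc$seed <- .derive_seed(train_cfg$seed, f)
      nc <- net_cfg
      nc$seed <- .derive_seed(net_cfg$seed, 50 + f)
      dset <- make_training_set(cohort[ids %in% train_ids], truth_maps, combo,
                                masked_inputs = tc$masked_inputs)
      fitted <- if (model == "unet") train_unet(dset, tc, nc)
                else train_mlp(dset, tc, nc)
    }
    for (id in test_ids) {
      sub <- cohort[[which(ids == id)]]
      pred <- switch(model,
        unet = {
          entry <- make_training_set(list(sub), truth_maps, combo,
                                     masked_inputs = train_cfg$masked_inputs)[[1]]
          sliding_window_map(fitted$model, entry, sub$roi, stride = stride)
        },
        mlp = {
          entry <- make_training_set(list(sub), truth_maps, combo,
                                     masked_inputs = train_cfg$masked_inputs)[[1]]
          voxelwise_map(fitted$model, entry, sub$roi)
        },
        nlls = {
          vols <- .combo_volumes(sub, combo)
          proto2 <- t1rho_protocol(c(0, combo$ik), sub$protocol$fsl)
          fit_volume(list(vols$i0, vols$ik), proto2, roi = sub$roi,
                     method = "nlls")
        })
      predictions[[id]] <- pred
      trained_without <- c(trained_without,
                           if (model == "nlls" || !(id %in% train_ids)) id)
      met <- compute_subject_metrics(pred, truth_maps[[id]], sub$roi)
      rows[[id]] <- cbind(id = id, fold = f, met)
    }
  }
  metrics <- do.call(rbind, rows[ids])
  rownames(metrics) <- NULL
  list(predictions = predictions, metrics = metrics,
       summary = summarize_cohort(metrics), folds = folds,
       truth_maps = truth_maps, model = model, combo = combo)
}
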