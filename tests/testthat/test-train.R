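test_that("stratified folds partition subjects with balanced strata", {
  ids <- sprintf("s%02d", 1:40)
  strata <- rep(c("patient", "volunteer"), c(30, 10))
  f <- make_folds(ids, strata, 5, seed = 3)
  sizes <- tabulate(f$assignments, 5)
  expect_equal(sizes, rep(8, 5))
  for (k in 1:5) {
    members <- names(f$assignments)[f$assignments == k]
    expect_equal(sum(strata[match(members, ids)] == "volunteer"), 2)
  }
  # partition properties
  expect_setequal(names(f$assignments), ids)
  expect_true(all(f$assignments %in% 1:5))
  expect_identical(make_folds(ids, strata, 5, seed = 3)$assignments,
                   f$assignments)
  expect_false(identical(make_folds(ids, strata, 5, seed = 4)$assignments,
                         f$assignments))
  expect_error(make_folds(ids, strata, 1, seed = 1), "at least 2")
  expect_error(make_folds(ids[1:3], strata[1:3], 5, seed = 1), "more folds")
})

test_that("fold sizes stay within one of each other for awkward cohorts", {
  ids <- sprintf("s%02d", 1:13)
  strata <- rep(c("a", "b", "c"), c(6, 4, 3))
  f <- make_folds(ids, strata, 4, seed = 9)
  sizes <- tabulate(f$assignments, 4)
  expect_lte(diff(range(sizes)), 1)
})

test_that("patch sampling honors bounds, bias and determinism", {
  cfg <- train_config(patch_size = 16, roi_bias = 1, epochs = 1, seed = 1)
  H <- 40; W <- 48
  sp <- array(runif(2 * H * W), c(2, H, W))
  target <- matrix(runif(H * W), H, W)
  roi <- matrix(0, H, W); roi[18:22, 30:34] <- 1
  ps <- sample_patches(sp, target, roi, 20, cfg, seed = 5)
  for (p in ps) {
    expect_equal(dim(p$input), c(2, 16, 16))
    expect_gte(min(p$corner), 1)
    expect_lte(p$corner[1], H - 16 + 1)
    expect_lte(p$corner[2], W - 16 + 1)
    expect_gt(sum(p$roi), 0)       # roi_bias = 1: every patch touches the ROI
  }
  ps2 <- sample_patches(sp, target, roi, 20, cfg, seed = 5)
  expect_identical(ps, ps2)
  expect_error(sample_patches(sp, target, roi, 1,
                              train_config(patch_size = 64, epochs = 1)),
               "smaller")
})

test_that("augmentation is identity at zero config and exact under flips", {
  input <- array(runif(2 * 12 * 12), c(2, 12, 12))
  target <- matrix(runif(144), 12, 12)
  roi <- matrix(rbinom(144, 1, 0.3), 12, 12)
  id_cfg <- augment_config(0, 0, 0, 0)
  a <- augment_patch(input, target, id_cfg, seed = 1, roi = roi)
  expect_identical(a$input, input)
  expect_identical(a$target, target)
  expect_identical(a$roi, roi)
  # flips are exact reversals: flipping twice restores the input
  flip_cfg <- augment_config(flip = 1, rotation = 0, translation = 0,
                             gaussian_noise_sigma = 0)
  b <- augment_patch(input, target, flip_cfg, seed = 2, roi = roi)
  b2 <- augment_patch(b$input, b$target, flip_cfg, seed = 3, roi = b$roi)
  expect_equal(b2$input, input)
  expect_equal(b2$target, target)
  # geometry moves input and target together: with both flips forced,
  # every plane is reversed along both axes
  expect_identical(b$target, target[12:1, 12:1])
  expect_identical(b$input[2, , ], input[2, 12:1, 12:1])
  expect_identical(augment_patch(input, target, augment_config(), seed = 7),
                   augment_patch(input, target, augment_config(), seed = 7))
  # noise goes to inputs only
  noise_cfg <- augment_config(0, 0, 0, gaussian_noise_sigma = 0.1)
  d <- augment_patch(input, target, noise_cfg, seed = 4)
  expect_false(identical(d$input, input))
  expect_identical(d$target, target)
})

test_that("ROI masking zeroes exactly the non-ROI voxels", {
  co <- small_cohort(n = 1, seed = 21)
  sub <- co[[1]]
  masked <- mask_to_roi(sub$volumes, sub$roi)
  lab <- roi_labels(sub$roi)
  for (i in seq_along(masked)) {
    expect_true(all(masked[[i]]$data[lab == 0] == 0))
    expect_identical(masked[[i]]$data[lab > 0], sub$volumes[[i]]$data[lab > 0])
  }
  allzero <- roi_mask(array(0L, dim(lab)))
  expect_true(all(mask_to_roi(sub$volumes[[1]], allzero)$data == 0))
  small <- roi_mask(array(0L, c(1, 2, 2)))
  expect_error(mask_to_roi(sub$volumes[[1]], small), "mismatch")
})

test_that("learning rate decays exponentially per epoch", {
  cfg <- train_config(lr0 = 1e-3, lr_decay = 0.9, epochs = 5)
  lrs <- vapply(1:5, function(e) t1rhomap:::.lr_at(cfg, e), 0)
  expect_equal(lrs[1], 1e-3)
  expect_equal(lrs[-1] / lrs[-5], rep(0.9, 4), tolerance = 1e-12)
})

test_that("MLP training decreases the loss and honors the batch size", {
  co <- small_cohort(n = 2, seed = 22, snr = Inf)
  truth <- lapply(co, function(s) s$truth)
  names(truth) <- vapply(co, function(s) s$id, "")
  dset <- make_training_set(co, truth, list(i0 = "tsl0", ik = 50))
  cfg <- train_config(optimizer = "rmsprop", epochs = 25, batch_size = 128,
                      seed = 2)
  r <- train_mlp(dset, cfg, mlp_config(n_blocks = 2, width = 16, seed = 3))
  expect_lt(r$history[25], r$history[1])
  expect_equal(attr(r$history, "batch_size"), 128)
  n_roi <- sum(vapply(dset, function(d) sum(d$roi > 0 & d$valid), 0L))
  expect_equal(attr(r$history, "n_batches"), n_roi %/% 128)
  expect_gte(n_roi %/% 128, 2)
  # determinism end to end
  r2 <- train_mlp(dset, cfg, mlp_config(n_blocks = 2, width = 16, seed = 3))
  expect_identical(r$history, r2$history)
  expect_identical(r$model$head$W, r2$model$head$W)
  # degenerate inputs
  empty <- lapply(dset, function(d) { d$roi[] <- 0L; d })
  expect_error(train_mlp(empty, cfg, mlp_config(seed = 1)), "no ROI voxels")
  expect_error(train_mlp(list(), cfg, mlp_config(seed = 1)), "empty")
})

test_that("U-Net training runs deterministically and learns", {
  co <- small_cohort(n = 2, seed = 23, snr = Inf)
  truth <- nlls_truth_maps(co)
  dset <- make_training_set(co, truth, list(i0 = "tsl0", ik = 50))
  cfg <- train_config(optimizer = "adam", lr0 = 2e-3, lr_decay = 0.97,
                      epochs = 50, batch_size = 8, patch_size = 32,
                      patches_per_slice = 4, roi_loss_only = TRUE, seed = 4)
  ucfg <- unet_config(depth = 2, base_channels = 3, patch_size = 32, seed = 5)
  r <- train_unet(dset, cfg, ucfg)
  expect_length(r$history, 50)
  expect_lt(mean(tail(r$history, 5)), mean(r$history[1:3]))
  r2 <- train_unet(dset, cfg, ucfg)
  expect_identical(r$history, r2$history)
  expect_identical(r$model$head$W, r2$model$head$W)
})

test_that("with roi_loss_only the loss ignores non-ROI target voxels", {
  co <- small_cohort(n = 1, seed = 24)
  truth <- nlls_truth_maps(co)
  cfg <- train_config(optimizer = "adam", epochs = 3, batch_size = 8,
                      patch_size = 32, patches_per_slice = 2,
                      roi_loss_only = TRUE, seed = 6)
  ucfg <- unet_config(depth = 2, base_channels = 3, patch_size = 32, seed = 7)
  dset <- make_training_set(co, truth, list(i0 = "tsl0", ik = 50))
  r1 <- train_unet(dset, cfg, ucfg)
  # scramble every non-ROI target voxel: the training trace must not change
  truth2 <- truth
  lab <- roi_labels(co[[1]]$roi)
  set.seed(99)
  truth2[[1]]$values[lab == 0] <- runif(sum(lab == 0), 1, 500)
  dset2 <- make_training_set(co, truth2, list(i0 = "tsl0", ik = 50))
  r2 <- train_unet(dset2, cfg, ucfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$head$W, r2$model$head$W)
  # all-zero ROI is a hard error
  zero <- lapply(dset, function(d) { d$roi[] <- 0L; d })
  expect_error(train_unet(zero, cfg, ucfg), "no voxels|no ROI")
})

test_that("cross-validation predicts every subject once, by an unseen model", {
  co <- small_cohort(n = 6, seed = 25)
  ids <- vapply(co, function(s) s$id, "")
  strata <- vapply(co, function(s) s$stratum, "")
  folds <- make_folds(ids, strata, 3, seed = 1)
  res <- run_cross_validation(co, folds, model = "nlls",
                              combo = list(i0 = "tsl0", ik = 50))
  expect_setequal(res$metrics$id, ids)
  expect_equal(nrow(res$metrics), 6)
  expect_length(res$predictions, 6)
  # each subject was evaluated in its own assigned fold
  expect_equal(res$metrics$fold[match(names(folds$assignments),
                                      res$metrics$id)],
               unname(folds$assignments))
  expect_error(run_cross_validation(co, folds, model = "mlp",
                                    combo = list(i0 = "pd", ik = 0)),
               "not a valid")
})
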