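#' Read / write a weighted volume as NIfTI-1 with a JSON sidecar
#'
#' The 3D intensity grid goes into `.nii`/`.nii.gz`; the contrast tag, TSL and
#' voxel spacing go into a JSON sidecar next to it (same basename). The round
#' trip is lossless for grid, spacing and sidecar fields.
#'
#' @param path NIfTI file path.
#' @return `read_volume` returns a [weighted_volume()]; a missing sidecar
#'   yields a warning and an untagged volume.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  arr <- array(as.numeric(RNifti::readNifti(path)), dim(RNifti::readNifti(path)))
  sc_path <- .sidecar_path(path)
  if (!file.exists(sc_path)) {
    warning("missing sidecar for ", path, "; returning an untagged volume")
    return(weighted_volume(arr, contrast = 0))
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  contrast <- if (identical(sc$contrast, "pd")) "pd" else as.numeric(sc$tsl)
  weighted_volume(arr, contrast = contrast,
                  voxel_spacing = as.numeric(sc$voxel_spacing %||% c(1, 1, 1)))
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname read_volume
#' @param vol A [weighted_volume()].
#' @param subject_id Optional id recorded in the sidecar.
#' @export
write_volume <- function(vol, path, subject_id = NULL) {
  stopifnot(inherits(vol, "weighted_volume"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(vol$data, pixdim = vol$voxel_spacing), path)
  sc <- list(contrast = vol$contrast,
             tsl = if (vol$contrast == "t1rho") vol$tsl else NULL,
             voxel_spacing = vol$voxel_spacing,
             subject = subject_id, units = "arbitrary")
  jsonlite::write_json(sc[!vapply(sc, is.null, TRUE)], .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a labeled ROI mask as NIfTI-1
#'
#' @param path NIfTI file path.
#' @return `read_roi_mask` returns a [roi_mask()].
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  arr <- RNifti::readNifti(path)
  roi_mask(array(as.integer(round(arr)), dim(arr)))
}

#' @rdname read_roi_mask
#' @param mask A [roi_mask()].
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(mask$labels, datatype = "int16"), path)
  invisible(path)
}

#' Write a phantom cohort to a BIDS-like folder tree
#'
#' One folder per subject holding the T1rho-weighted volumes (with sidecars),
#' the PD surrogate, the labeled cartilage mask and the ground-truth map.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (sub in cohort) {
    sd <- file.path(dir, sub$id)
    for (v in sub$volumes)
      write_volume(v, file.path(sd, sprintf("%s_tsl-%g.nii.gz", sub$id, v$tsl)),
                   subject_id = sub$id)
    write_volume(sub$pd_volume, file.path(sd, sprintf("%s_pd.nii.gz", sub$id)),
                 subject_id = sub$id)
    write_roi_mask(sub$roi, file.path(sd, sprintf("%s_roi.nii.gz", sub$id)))
    tm <- RNifti::asNifti(sub$truth$values)
    RNifti::writeNifti(tm, file.path(sd, sprintf("%s_truth.nii.gz", sub$id)))
    jsonlite::write_json(list(id = sub$id, stratum = sub$stratum,
                              tsls = sub$protocol$tsls, fsl = sub$protocol$fsl),
                         file.path(sd, sprintf("%s_meta.json", sub$id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Desk-scale training profile
#'
#' Problem sizes chosen so that a full simulate / cross-validate / evaluate
#' cycle runs on one CPU core in minutes: a depth-2, 4-channel 2D U-Net
#' (batches of 8 patches, 2 patches per ROI slice per epoch) and the default
#' 4x64 MLP, both trained for 200 epochs with the published optimizer
#' settings (Adam / RMSProp, initial learning rate 1e-3, per-epoch decay
#' 0.9, weight decay 3e-4; 512 voxel rows per MLP batch).
#'
#' @param seed Base seed propagated into every config.
#' @return List with `unet_cfg`, `mlp_cfg`, `unet_train`, `mlp_train`.
#' @export
fast_profile <- function(seed = 1L) {
  list(unet_cfg = unet_config(depth = 2, base_channels = 4, patch_size = 64,
                              seed = seed),
       mlp_cfg = mlp_config(n_blocks = 4, width = 64, seed = seed),
       unet_train = train_config(optimizer = "adam", epochs = 200,
                                 batch_size = 8, patches_per_slice = 2,
                                 seed = seed),
       mlp_train = train_config(optimizer = "rmsprop", epochs = 200,
                                batch_size = 512, seed = seed))
}

.run_config_keys <- c("out_dir", "cohort_root", "model", "combo", "masked",
                      "roi_loss_only", "seed", "n_subjects", "k_folds", "snr",
                      "fast", "stride", "write_volumes")

#' Load and validate a run configuration
#'
#' YAML (or JSON) with strict key checking; unknown keys are rejected, and an
#' I0/Ik combination outside the six legal ones is rejected with the legal
#' list. Defaults: 12 subjects, 3 folds, SNR 30, MLP on (TSL 0, TSL 50),
#' fast profile, seed 1.
#'
#' @param path Path to a YAML or JSON config file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  as_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg A named list of config values.
#' @export
as_run_config <- function(cfg = list()) {
  defaults <- list(out_dir = "t1rho-run", cohort_root = NULL,
                   model = "mlp", combo = list(i0 = "tsl0", ik = 50),
                   masked = FALSE, roi_loss_only = FALSE, seed = 1L,
                   n_subjects = 12L, k_folds = 3L, snr = 30, fast = TRUE,
                   stride = 32L, write_volumes = FALSE)
  for (k in names(cfg)) defaults[k] <- cfg[k]   # [k]<- keeps explicit NULLs
  cfg <- defaults
  if (!cfg$model %in% c("unet", "mlp", "nlls"))
    stop("'model' must be unet, mlp or nlls")
  cfg$combo <- list(i0 = as.character(cfg$combo$i0), ik = as.numeric(cfg$combo$ik))
  .check_combo(cfg$combo, learner = cfg$model != "nlls")
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: simulate, fit or cross-validate, evaluate
#'
#' Generates the synthetic cohort, derives the 4-point NLLS ground truth,
#' runs the requested model (cross-validated for the learners, direct fitting
#' for NLLS), and writes the per-subject metrics, the cohort summary, the
#' fold assignments and a run log (seed, config, package version) into
#' `cfg$out_dir`. Two runs with identical config and seed produce identical
#' outputs. NLLS on a PD-weighted I0 runs but is flagged model-nonconforming
#' in the metrics table.
#'
#' @param cfg A `run_config` from [as_run_config()] or [load_run_config()].
#' @return Invisibly, the cross-validation result list (with `metrics` and
#'   `summary`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(snr = cfg$snr, seed = cfg$seed)
  protocol <- t1rho_protocol(c(0, 10, 30, 50))
  cohort <- generate_cohort(cfg$n_subjects, spec, protocol, seed = cfg$seed)
  if (cfg$write_volumes && !is.null(cfg$cohort_root))
    write_cohort(cohort, cfg$cohort_root)
  ids <- vapply(cohort, function(s) s$id, "")
  strata <- vapply(cohort, function(s) s$stratum, "")
  folds <- make_folds(ids, strata, cfg$k_folds, seed = cfg$seed)
  prof <- fast_profile(seed = cfg$seed)
  if (cfg$model == "unet") {
    tc <- prof$unet_train; nc <- prof$unet_cfg
  } else {
    tc <- prof$mlp_train; nc <- prof$mlp_cfg
  }
  tc$masked_inputs <- isTRUE(cfg$masked)
  tc$roi_loss_only <- isTRUE(cfg$roi_loss_only)
  res <- run_cross_validation(cohort, folds, model = cfg$model,
                              combo = cfg$combo, train_cfg = tc, net_cfg = nc,
                              stride = cfg$stride)
  nonconforming <- cfg$model == "nlls" && cfg$combo$i0 == "pd"
  res$metrics$model_nonconforming <- nonconforming
  utils::write.csv(res$metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(folds$assignments),
                       file.path(cfg$out_dir, "folds.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  log <- c(sprintf("t1rhomap %s", as.character(utils::packageVersion("t1rhomap"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("config_md5: %s", unname(tools::md5sum(tf))),
           sprintf("config: %s", cfg_json))
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  invisible(res)
}
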