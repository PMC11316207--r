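#' Reduced filter bank for CPU-scale runs
#'
#' One steerable scale and three Frangi/OOF scales on both branches
#' (98 features), preserving the structure of the full 354-feature bank at
#' a fraction of the cost.
#'
#' @return a [filter_bank_config()].
#' @export
desk_filter_bank <- function() {
  filter_bank_config(sf_sigmas_mm = 0.8,
                     ff_sigmas_mm = c(0.5, 1, 2),
                     oof_radii_mm = c(0.6, 1.2, 2.4))
}

#' Prepare a subject for training or inference
#'
#' Full per-subject preprocessing: robust Z-score normalization over the
#' hemisphere mask, optional denoising, multi-scale feature extraction,
#' per-subject PCA reduction, and assembly of the 19-channel network
#' input.
#'
#' @param phantom an `epvs_phantom`, or any list with `image`, `atlas`,
#'   `wm_mask`, `hemi_mask`, optional `gt_labels` and `id`.
#' @param fb_config a [filter_bank_config()] (default [desk_filter_bank()]).
#' @param n_components PCA components (default 12).
#' @param denoise_method passed to [denoise()].
#' @return a subject list: `id`, `inputs` (19-channel `epvs_stack`),
#'   `labels`, `wm`, `atlas`, `gt_labels`, `pca`.
#' @export
prepare_subject <- function(phantom, fb_config = desk_filter_bank(),
                            n_components = 12,
                            denoise_method = "none") {
  norm <- robust_z_normalize(phantom$image, phantom$hemi_mask)
  norm <- denoise(norm, denoise_method)
  stack <- assemble_feature_stack(norm, fb_config)
  pca <- fit_pca(stack, phantom$hemi_mask, n_components)
  feats <- transform_pca(stack, pca)
  inputs <- network_inputs(norm, feats, phantom$wm_mask, phantom$atlas)
  labels <- if (!is.null(phantom$gt_labels))
    epvs_mask(phantom$gt_labels$grid > 0L, phantom$image$geometry)
  list(id = phantom$id %||% "S01", inputs = inputs, labels = labels,
       wm = phantom$wm_mask, atlas = phantom$atlas,
       gt_labels = phantom$gt_labels, pca = pca)
}

#' Run a pipeline subcommand
#'
#' Config-driven orchestration of the pipeline stages. Each subcommand
#' reads and writes only declared artifacts under `output_dir` and leaves
#' a JSON run manifest (config hash, seed, timing) next to its outputs.
#'
#' Subcommands: `simulate` (phantom cohort as NIfTI sets), `preprocess`
#' (robust-Z volumes), `features` (PCA feature maps), `train` (LOOCV
#' ensemble checkpoint), `calibrate` (lobe-erasure threshold), `predict`
#' (probability maps and masks), `evaluate` (ROI evaluation report),
#' `quantify` (per-subject counts/densities/bins CSV).
#'
#' @param name subcommand name.
#' @param config a configuration list or path to a YAML file; see
#'   [default_pipeline_config()].
#' @param output_dir output directory (created if needed).
#' @param seed master seed (overrides the config seed if given).
#' @param desk_scale apply the reduced network/training settings.
#' @return invisibly, a list of produced artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "preprocess", "features",
                                    "train", "calibrate", "predict",
                                    "evaluate", "quantify"),
                           config = default_pipeline_config(),
                           output_dir = "epvseg-out", seed = NULL,
                           desk_scale = TRUE) {
  name <- match.arg(name)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  arts <- switch(name,
    simulate = sc_simulate(config, output_dir),
    preprocess = sc_preprocess(config, output_dir),
    features = sc_features(config, output_dir),
    train = sc_train(config, output_dir, desk_scale),
    calibrate = sc_calibrate(config, output_dir, desk_scale),
    predict = sc_predict(config, output_dir),
    evaluate = sc_evaluate(config, output_dir),
    quantify = sc_quantify(config, output_dir))
  manifest <- list(subcommand = name, seed = config$seed,
                   config_hash = config_hash(config),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   artifacts = arts,
                   package_version = as.character(utils::packageVersion("epvseg")))
  jsonlite::write_json(manifest,
                       file.path(output_dir,
                                 paste0("manifest-", name, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(arts)
}

#' Default pipeline configuration
#'
#' @param n_subjects cohort size for `simulate`.
#' @param seed master seed.
#' @return nested configuration list (serializable to YAML).
#' @export
default_pipeline_config <- function(n_subjects = 4L, seed = 1L) {
  list(seed = as.integer(seed),
       cohort = list(n_subjects = as.integer(n_subjects),
                     shape = c(48L, 48L, 24L),
                     meanlog = log(20), sdlog = 0.4),
       features = list(n_components = 12L),
       network = list(betas = c(10, 0.1, 1), epsilon = 1e-3,
                      dropconnect_p = 0.3, l2_weight = 0.001),
       ensemble = list(threshold = 0.2))
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path")
  base <- default_pipeline_config()
  for (k in names(base))
    if (is.null(config[[k]])) config[[k]] <- base[[k]]
  b <- config$network$betas
  if (length(b) != 3 || any(!is.finite(b)) || any(b <= 0))
    stop("config field network.betas: need three positive values")
  if (config$ensemble$threshold <= 0 || config$ensemble$threshold >= 1)
    stop("config field ensemble.threshold: must be in (0,1)")
  if (config$cohort$n_subjects < 2)
    stop("config field cohort.n_subjects: need at least 2")
  config
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small deterministic polynomial content hash; avoids extra dependencies
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

cohort_from_config <- function(config) {
  shape <- as.integer(config$cohort$shape)
  ext <- shape * c(0.6, 0.6, 1.5)
  cfg <- phantom_config(shape = shape,
                        region_counts = c(frontal = 8L, parietal = 5L,
                                          temporal = 3L, occipital = 2L,
                                          basal_ganglia = 5L),
                        length_range_mm = c(2, min(15, min(ext) / 3)))
  make_cohort(config$cohort$n_subjects, seed = config$seed,
              base_config = cfg, meanlog = config$cohort$meanlog,
              sdlog = config$cohort$sdlog)
}

sc_simulate <- function(config, out) {
  cohort <- cohort_from_config(config)
  paths <- character()
  for (ph in cohort) {
    base <- file.path(out, ph$id)
    dir.create(base, showWarnings = FALSE)
    p <- c(image = file.path(base, "image.nii.gz"),
           atlas = file.path(base, "atlas.nii.gz"),
           wm = file.path(base, "wm.nii.gz"),
           hemi = file.path(base, "hemi.nii.gz"),
           gt = file.path(base, "gt_labels.nii.gz"))
    write_volume(ph$image, p["image"])
    write_volume(ph$atlas, p["atlas"])
    write_volume(epvs_volume(ph$wm_mask$grid * 1, ph$image$geometry), p["wm"])
    write_volume(epvs_volume(ph$hemi_mask$grid * 1, ph$image$geometry), p["hemi"])
    write_volume(epvs_volume(ph$gt_labels$grid * 1, ph$image$geometry), p["gt"])
    utils::write.csv(ph$instances, file.path(base, "instances.csv"),
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

load_cohort_subjects <- function(config) {
  cohort <- cohort_from_config(config)
  lapply(cohort, prepare_subject,
         n_components = config$features$n_components)
}

sc_preprocess <- function(config, out) {
  cohort <- cohort_from_config(config)
  paths <- character()
  for (ph in cohort) {
    norm <- robust_z_normalize(ph$image, ph$hemi_mask)
    p <- file.path(out, paste0(ph$id, "-norm.nii.gz"))
    write_volume(norm, p)
    paths <- c(paths, p)
  }
  paths
}

sc_features <- function(config, out) {
  cohort <- cohort_from_config(config)
  paths <- character()
  for (ph in cohort) {
    s <- prepare_subject(ph, n_components = config$features$n_components)
    p <- file.path(out, paste0(ph$id, "-pca.nii.gz"))
    arr <- array(s$inputs$data[, 2:(1 + config$features$n_components)],
                 c(s$inputs$dims, config$features$n_components))
    RNifti::writeNifti(RNifti::asNifti(arr,
                                       pixdim = s$inputs$geometry$spacing_mm), p)
    paths <- c(paths, p)
  }
  paths
}

sc_train <- function(config, out, desk_scale) {
  subs <- load_cohort_subjects(config)
  ds <- desk_scale_settings(config, desk_scale)
  ens <- train_ensemble_loocv(subs, ds$net, ds$train,
                              threshold = config$ensemble$threshold)
  p <- file.path(out, "ensemble.rds")
  saveRDS(ens, p)
  p
}

desk_scale_settings <- function(config, use_desk) {
  dsl <- if (use_desk) desk_scale(config$seed)
         else list(net = network_config(), train = training_config(seed = config$seed))
  dsl$net$betas <- config$network$betas
  dsl$net$epsilon <- config$network$epsilon
  dsl$net$dropconnect_p <- config$network$dropconnect_p
  dsl$net$l2_weight <- config$network$l2_weight
  # optional size overrides (e.g. for quick smoke runs of the chain)
  for (k in intersect(names(config$train %||% list()),
                      c("epochs", "batches_per_epoch", "batch_size",
                        "patch_size", "val_every", "val_overlap")))
    dsl$train[[k]] <- config$train[[k]]
  for (k in intersect(names(config$network),
                      c("base_channels", "convs_per_level")))
    dsl$net[[k]] <- as.integer(config$network[[k]])
  dsl$train$seed <- config$seed
  dsl
}

sc_calibrate <- function(config, out, desk_scale) {
  subs <- load_cohort_subjects(config)
  ds <- desk_scale_settings(config, desk_scale)
  thr <- calibrate_threshold(subs, n_repeats = 2, net_config = ds$net,
                             train_config = ds$train, seed = config$seed)
  p <- file.path(out, "threshold.json")
  jsonlite::write_json(list(threshold = as.numeric(thr),
                            per_repeat = as.numeric(attr(thr, "per_repeat"))),
                       p, auto_unbox = TRUE, digits = NA)
  p
}

require_ensemble <- function(out) {
  p <- file.path(out, "ensemble.rds")
  if (!file.exists(p))
    stop("missing upstream artifact: ", p, " (run the 'train' subcommand first)")
  readRDS(p)
}

sc_predict <- function(config, out) {
  ens <- require_ensemble(out)
  subs <- load_cohort_subjects(config)
  paths <- character()
  for (s in subs) {
    pr <- predict(ens, s)
    pp <- file.path(out, paste0(s$id, "-prob.nii.gz"))
    pm <- file.path(out, paste0(s$id, "-mask.nii.gz"))
    write_volume(pr$prob, pp)
    write_volume(epvs_volume(pr$mask$grid * 1, pr$prob$geometry), pm)
    paths <- c(paths, pp, pm)
  }
  paths
}

sc_evaluate <- function(config, out) {
  ens <- require_ensemble(out)
  subs <- load_cohort_subjects(config)
  set.seed(config$seed)
  rois <- generate_rois(subs, n_per_region = 1, roi_size = c(25, 25, 9),
                        one_per_subject = FALSE)
  preds <- lapply(subs, function(s) predict(ens, s)$mask)
  names(preds) <- vapply(subs, `[[`, "", "id")
  rep <- evaluate_ensemble(preds, subs, rois)
  pj <- file.path(out, "evaluation.json")
  jsonlite::write_json(list(sensitivity = as.list(rep$sensitivity),
                            dsc = rep$dsc,
                            count_correlation = rep$count_correlation),
                       pj, auto_unbox = TRUE, digits = NA)
  pc <- file.path(out, "per_roi.csv")
  utils::write.csv(rep$per_roi, pc, row.names = FALSE)
  c(pj, pc)
}

sc_quantify <- function(config, out) {
  ens <- require_ensemble(out)
  subs <- load_cohort_subjects(config)
  sums <- list()
  for (s in subs) {
    pr <- predict(ens, s)
    inst <- extract_instances(pr$mask)
    sums[[s$id]] <- summarize_epvs(inst, s$atlas)
  }
  p <- file.path(out, "epvs_summary.csv")
  utils::write.csv(epvs_subject_table(sums), p, row.names = FALSE)
  p
}
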