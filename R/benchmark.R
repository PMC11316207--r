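#' Desk-scale end-to-end benchmark
#'
#' Runs the full pipeline at CPU scale: generates a small phantom cohort,
#' prepares features, trains a leave-one-out ensemble at the reduced
#' settings ([desk_scale()]: 16 base channels, 32 x 32 x 16 patches,
#' 40 epochs x 10 batches), and evaluates on one additional fresh phantom
#' never used in training. Reports the held-out whole-volume Dice
#' coefficient (probabilities thresholded at 0.5, the same convention the
#' early-stopping metric uses) and the instance detection rate at the
#' ensemble threshold, overall and for instances larger than 12 mm^3.
#'
#' @param seed master seed; controls phantom generation, initialization,
#'   sampling and DropConnect.
#' @param n_train training phantoms for the LOOCV ensemble (default 4).
#' @param shape phantom grid (default 48 x 48 x 24 voxels).
#' @param threshold ensemble probability threshold (default 0.2).
#' @param verbose print member progress.
#' @return list with `heldout_dsc`, `detection_overall`,
#'   `detection_large`, the `ensemble`, the detection `records` and the
#'   per-member validation summary.
#' @export
desk_benchmark <- function(seed = 11L, n_train = 4L,
                           shape = c(48L, 48L, 24L), threshold = 0.2,
                           verbose = FALSE) {
  cfg <- phantom_config(shape = shape,
                        region_counts = c(frontal = 8L, parietal = 5L,
                                          temporal = 3L, occipital = 2L,
                                          basal_ganglia = 5L),
                        n_large_guaranteed = 2L)
  phs <- lapply(seq_len(n_train + 1L), function(i) {
    p <- make_phantom(cfg, seed = (seed * 101L + i) %% .Machine$integer.max)
    p$id <- sprintf("P%02d", i)
    p
  })
  subs <- lapply(phs, prepare_subject)
  ds <- desk_scale(seed = seed)
  tc <- ds$train
  tc$batch_size <- 1L
  tc$val_every <- 10L
  ens <- train_ensemble_loocv(subs[seq_len(n_train)], ds$net, tc,
                              threshold = threshold, verbose = verbose)
  fresh <- subs[[n_train + 1L]]
  pr <- predict(ens, fresh)
  hard <- epvs_mask(pr$prob$grid >= 0.5, pr$prob$geometry)
  dims <- fresh$inputs$dims
  whole <- data.frame(subject = fresh$id, region = 1, region_name = "all",
                      x0 = 1, y0 = 1, z0 = 1,
                      sx = dims[1], sy = dims[2], sz = dims[3], roi = 1)
  rec <- match_detections(phs[[n_train + 1L]]$gt_labels, pr$mask, whole)
  sens <- sensitivity(rec, c(0, 3, 12))
  list(heldout_dsc = dsc(hard, fresh$labels),
       detection_overall = unname(sens[">0mm3"]),
       detection_large = unname(sens[">12mm3"]),
       sensitivity = sens,
       ensemble = ens,
       records = rec,
       members = data.frame(
         held_out = vapply(ens$members, `[[`, "", "held_out"),
         best_epoch = vapply(ens$members, `[[`, 1L, "best_epoch"),
         best_validation_dsc = vapply(ens$members, `[[`, 1,
                                      "best_validation_dsc")))
}
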