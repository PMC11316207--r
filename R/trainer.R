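#' Training configuration
#'
#' Defaults follow the full-scale protocol: 1200 epochs of 40 batches with
#' 8 samples each, 64 x 64 x 24 patches centred at white-matter voxels,
#' stochastic gradient descent with learning rate 0.001 and Nesterov
#' momentum 0.9, L2 weight decay 0.001 on convolution kernels and
#' DropConnect probability 0.3. `desk_scale()` provides reduced settings
#' for single-CPU runs.
#'
#' @param epochs number of epochs.
#' @param batches_per_epoch batches per epoch.
#' @param batch_size patches per batch.
#' @param patch_size integer length-3, divisible by 8.
#' @param learning_rate SGD learning rate.
#' @param nesterov_momentum momentum coefficient.
#' @param l2 weight decay on convolution kernels.
#' @param seed master seed for weight init, patch sampling and DropConnect.
#' @param val_every validate (and checkpoint) every this many epochs.
#' @param val_overlap window overlap fraction for validation inference.
#' @return a `training_config` object.
#' @export
training_config <- function(epochs = 1200L, batches_per_epoch = 40L,
                            batch_size = 8L, patch_size = c(64L, 64L, 24L),
                            learning_rate = 0.001, nesterov_momentum = 0.9,
                            l2 = 0.001, seed = 1L, val_every = 1L,
                            val_overlap = 0.5) {
  patch_size <- as.integer(patch_size)
  if (any(patch_size %% 8L != 0))
    stop("patch dimensions must be divisible by 2^3 (three downsamplings)")
  stopifnot(epochs >= 1, batches_per_epoch >= 1, batch_size >= 1,
            learning_rate > 0, nesterov_momentum >= 0, l2 >= 0)
  structure(list(epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 batch_size = as.integer(batch_size),
                 patch_size = patch_size, learning_rate = learning_rate,
                 nesterov_momentum = nesterov_momentum, l2 = l2,
                 seed = as.integer(seed), val_every = as.integer(val_every),
                 val_overlap = val_overlap),
            class = "training_config")
}

#' Reduced-scale configuration for CPU runs
#'
#' Scales down epochs, width and patch size only; the loss, architecture
#' semantics, learning rate and regularizers are unchanged.
#'
#' @param seed master seed.
#' @return list with `net` ([network_config()]) and `train`
#'   ([training_config()]) entries.
#' @export
desk_scale <- function(seed = 1L) {
  list(net = network_config(base_channels = 16L, convs_per_level = 1L),
       train = training_config(epochs = 40L, batches_per_epoch = 10L,
                               batch_size = 2L,
                               patch_size = c(32L, 32L, 16L),
                               seed = seed, val_every = 4L,
                               val_overlap = 0))
}

# reflect an arbitrary (possibly out-of-range) 1-based index vector into 1..n
reflect_clip <- function(i, n) {
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Sample a training patch centred at a white-matter voxel
#'
#' The centre is drawn uniformly over the subject's white-matter mask;
#' patches crossing the volume boundary are completed by reflect padding.
#' Uses the current R random-number state.
#'
#' @param subject a subject list with `inputs` (`epvs_stack`), `labels`
#'   (`epvs_mask`) and `wm` (`epvs_mask`); see [prepare_subject()].
#' @param patch_size integer length-3.
#' @return list with `x` (nvox x channels matrix with a `dims` attribute),
#'   `y` (binary label vector) and `center` (voxel index triple).
#' @export
sample_patch <- function(subject, patch_size = c(64L, 64L, 24L)) {
  wm <- which(subject$wm$grid)
  if (length(wm) == 0) stop("white-matter mask is empty")
  v <- wm[sample.int(length(wm), 1L)]
  dims <- subject$inputs$dims
  ctr <- arrayInd(v, dims)[1, ]
  half <- patch_size %/% 2L
  idx <- lapply(1:3, function(a)
    reflect_clip(ctr[a] - half[a] + seq_len(patch_size[a]), dims[a]))
  lin <- as.vector(outer(outer(idx[[1]],
                               (idx[[2]] - 1L) * dims[1], "+"),
                         (idx[[3]] - 1L) * dims[1] * dims[2], "+"))
  x <- subject$inputs$data[lin, , drop = FALSE]
  attr(x, "dims") <- as.integer(patch_size)
  y <- as.numeric(subject$labels$grid)[lin]
  list(x = x, y = y, center = ctr)
}

# Dice similarity between a probability map and labels at a threshold
val_dsc <- function(prob, labels, threshold = 0.5) {
  dsc(epvs_mask(prob$grid >= threshold, prob$geometry), labels)
}

#' Train one ensemble member
#'
#' Runs `epochs x batches_per_epoch x batch_size` patch steps of
#' SGD/Nesterov with L2 weight decay, DropConnect and batch normalization
#' on patches sampled from the training subjects; at every `val_every`-th
#' epoch records the validation loss (stage-2 F-beta, beta = 1, on the
#' whole validation volume) and the whole-volume Dice coefficient at
#' probability threshold 0.5, and finally returns the weights of the
#' DSC-maximizing recorded epoch (ties broken toward the earlier epoch).
#'
#' @param train_subjects list of subjects (see [prepare_subject()]).
#' @param val_subject held-out subject, distinct from the training set.
#' @param net_config a [network_config()].
#' @param train_config a [training_config()].
#' @param verbose print per-validation progress.
#' @return an `epvs_member`: snapshot of the best weights plus
#'   `held_out`, `best_epoch`, `best_validation_dsc` and the epoch
#'   `history` data frame.
#' @export
train_member <- function(train_subjects, val_subject,
                         net_config = network_config(),
                         train_config = training_config(),
                         verbose = FALSE) {
  if (length(train_subjects) < 1) stop("need at least one training subject")
  if (any(vapply(train_subjects, `[[`, "", "id") == val_subject$id))
    stop("validation subject also appears in the training set")
  tc <- train_config
  model <- build_model(net_config, seed = tc$seed)
  set.seed(tc$seed)
  vel <- new.env(parent = emptyenv())
  best <- list(dsc = -Inf, epoch = NA_integer_, pars = NULL, buffers = NULL)
  history <- NULL
  m <- tc$nesterov_momentum
  for (epoch in seq_len(tc$epochs)) {
    for (batch in seq_len(tc$batches_per_epoch)) {
      gacc <- list()
      loss_acc <- 0
      for (s in seq_len(tc$batch_size)) {
        subj <- train_subjects[[sample.int(length(train_subjects), 1L)]]
        p <- sample_patch(subj, tc$patch_size)
        fw <- forward_triple(model, p$x, training = TRUE)
        l <- total_loss(p$y, fw$pA, fw$pB, fw$pC, net_config)
        if (!is.finite(l))
          stop(sprintf("training diverged (non-finite loss at epoch %d, batch %d)",
                       epoch, batch))
        loss_acc <- loss_acc + l
        seeds <- list()
        seeds[[as.character(attr(fw$pA, "id"))]] <-
          matrix(fbeta_grad(p$y, fw$pA, net_config$betas[1],
                            net_config$epsilon) / tc$batch_size)
        seeds[[as.character(attr(fw$pB, "id"))]] <-
          matrix(fbeta_grad(p$y, fw$pB, net_config$betas[2],
                            net_config$epsilon) / tc$batch_size)
        seeds[[as.character(attr(fw$pC, "id"))]] <-
          matrix(fbeta_grad(p$y, fw$pC, net_config$betas[3],
                            net_config$epsilon) / tc$batch_size)
        pg <- backprop(fw$tape, seeds)
        for (nm in names(pg))
          gacc[[nm]] <- if (is.null(gacc[[nm]])) pg[[nm]] else gacc[[nm]] + pg[[nm]]
      }
      for (nm in names(gacc)) {
        g <- gacc[[nm]]
        if (identical(model$kind[[nm]], "convW"))
          g <- g + tc$l2 * model$pars[[nm]]
        v <- get0(nm, envir = vel, inherits = FALSE)
        if (is.null(v)) v <- 0
        v <- m * v + g
        vel[[nm]] <- v
        model$pars[[nm]] <- model$pars[[nm]] - tc$learning_rate * (g + m * v)
      }
    }
    if (epoch %% tc$val_every == 0L || epoch == tc$epochs) {
      prob <- predict_volume(model, val_subject$inputs, tc$patch_size,
                             tc$val_overlap)
      d <- val_dsc(prob, val_subject$labels, 0.5)
      vloss <- fbeta_loss(as.numeric(val_subject$labels$grid),
                          as.numeric(prob$grid), 1, net_config$epsilon)
      history <- rbind(history,
                       data.frame(epoch = epoch, val_dsc = d,
                                  val_loss = vloss,
                                  train_loss = loss_acc / tc$batch_size))
      if (verbose)
        message(sprintf("  epoch %4d  val DSC %.3f  val loss %.3f",
                        epoch, d, vloss))
      if (d > best$dsc) {
        best <- list(dsc = d, epoch = epoch,
                     pars = as.list(model$pars),
                     buffers = as.list(model$buffers))
      }
    }
  }
  structure(list(pars = best$pars, buffers = best$buffers,
                 kind = as.list(model$kind), cfg = net_config,
                 held_out = val_subject$id, best_epoch = best$epoch,
                 best_validation_dsc = best$dsc, history = history),
            class = "epvs_member")
}

# rebuild a runnable model from a member snapshot
member_model <- function(member) {
  model <- new.env(parent = emptyenv())
  model$cfg <- member$cfg
  model$pars <- list2env(member$pars, parent = emptyenv())
  model$buffers <- list2env(member$buffers, parent = emptyenv())
  model$kind <- list2env(member$kind, parent = emptyenv())
  model$n_parameters <- sum(vapply(member$pars, length, 1))
  class(model) <- "epvs_segmodel"
  model
}

#' Train a LOOCV ensemble
#'
#' One member per subject, that subject held out for validation-based
#' early stopping; member order is deterministic by subject id. The
#' ensemble prediction averages member probability maps and thresholds
#' them (default threshold 0.2; see [calibrate_threshold()]).
#'
#' @param subjects list of labelled subjects (>= 2).
#' @param net_config a [network_config()].
#' @param train_config a [training_config()]; member seeds are derived
#'   deterministically from `train_config$seed`.
#' @param threshold ensemble probability threshold.
#' @param verbose print progress.
#' @return an `epvs_ensemble` object.
#' @export
train_ensemble_loocv <- function(subjects, net_config = network_config(),
                                 train_config = training_config(),
                                 threshold = 0.2, verbose = FALSE) {
  if (length(subjects) < 2) stop("LOOCV needs at least 2 subjects")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  subjects <- subjects[order(ids)]
  members <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    if (verbose) message("training member ", i, " (holding out ",
                         subjects[[i]]$id, ")")
    tci <- train_config
    tci$seed <- (train_config$seed * 131L + i) %% .Machine$integer.max
    members[[i]] <- train_member(subjects[-i], subjects[[i]],
                                 net_config, tci, verbose = verbose)
  }
  structure(list(members = members, threshold = threshold,
                 net_config = net_config, train_config = train_config),
            class = "epvs_ensemble")
}

#' @export
print.epvs_ensemble <- function(x, ...) {
  cat(sprintf("epvs_ensemble: %d LOOCV members, probability threshold %.2f\n",
              length(x$members), x$threshold))
  invisible(x)
}

#' @export
summary.epvs_ensemble <- function(object, ...) {
  df <- data.frame(
    held_out = vapply(object$members, `[[`, "", "held_out"),
    best_epoch = vapply(object$members, `[[`, 1L, "best_epoch"),
    best_validation_dsc = vapply(object$members, `[[`, 1, "best_validation_dsc"))
  cat(sprintf("LOOCV ensemble of %d members, threshold %.2f\n",
              length(object$members), object$threshold))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Ensemble prediction for one subject
#'
#' Voxel-wise mean of the member probability maps, thresholded at the
#' ensemble threshold.
#'
#' @param object an `epvs_ensemble`.
#' @param inputs the subject's 19-channel `epvs_stack`
#'   (see [network_inputs()]), or a subject list carrying `$inputs`.
#' @param patch_size,overlap_fraction inference tiling (defaults: the
#'   training patch size, overlap 0.5).
#' @param ... unused.
#' @return list with `prob` (`epvs_volume`) and `mask` (`epvs_mask`,
#'   probability >= threshold).
#' @export
predict.epvs_ensemble <- function(object, inputs,
                                  patch_size = NULL,
                                  overlap_fraction = 0.5, ...) {
  if (!inherits(inputs, "epvs_stack") && !is.null(inputs$inputs))
    inputs <- inputs$inputs
  if (is.null(patch_size)) patch_size <- object$train_config$patch_size
  acc <- NULL
  for (mb in object$members) {
    pm <- predict_volume(member_model(mb), inputs, patch_size,
                         overlap_fraction)
    acc <- if (is.null(acc)) pm$grid else acc + pm$grid
  }
  prob <- epvs_volume(acc / length(object$members), inputs$geometry)
  list(prob = prob,
       mask = epvs_mask(prob$grid >= object$threshold, inputs$geometry))
}

# erase one lobe from a subject: zero the network inputs and the labels in
# the lobe, and remove the lobe from the patch-sampling WM mask
erase_lobe <- function(subject, lobe) {
  sel <- subject$atlas$grid == lobe
  s <- subject
  s$inputs$data[as.vector(sel), ] <- 0
  s$labels$grid[sel] <- FALSE
  s$wm$grid[sel] <- FALSE
  s$erased <- sel
  s
}

#' Calibrate the ensemble probability threshold by lobe erasure
#'
#' For each of `n_repeats` repeats: one randomly chosen lobe is erased
#' from every subject (intensities and labels zeroed and excluded from
#' patch sampling), an LOOCV ensemble is trained on the erased data, and
#' the grid threshold maximizing the Dice coefficient pooled over the
#' erased-lobe voxels of all subjects is recorded (ties broken toward the
#' lowest grid value). The calibrated threshold is the mean of the
#' per-repeat optima.
#'
#' @param subjects labelled subjects carrying an `atlas` entry.
#' @param n_repeats number of erasure repeats (default 5).
#' @param threshold_grid candidate thresholds.
#' @param net_config,train_config model/training settings for the erased
#'   ensembles.
#' @param seed seed for the lobe draws.
#' @param train_fn function(subjects) returning either an object whose
#'   [predict()] yields `$prob` for a subject, or directly a
#'   function(subject) with the same return; defaults to LOOCV ensemble
#'   training and exists so a perfect-oracle predictor can be injected in
#'   degenerate-case tests.
#' @return scalar calibrated threshold, with the per-repeat optima in
#'   `attr(, "per_repeat")`.
#' @export
calibrate_threshold <- function(subjects, n_repeats = 5,
                                threshold_grid = seq(0.05, 0.95, by = 0.05),
                                net_config = network_config(),
                                train_config = training_config(),
                                seed = 1L, train_fn = NULL) {
  if (is.null(train_fn))
    train_fn <- function(subs) train_ensemble_loocv(subs, net_config,
                                                    train_config)
  set.seed(seed)
  opts <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    lobes <- sample(1:5, length(subjects), replace = TRUE)
    erased <- Map(erase_lobe, subjects, lobes)
    n_gt <- sum(vapply(seq_along(subjects), function(i)
      sum(subjects[[i]]$labels$grid[erased[[i]]$erased]), 1))
    if (n_gt == 0)
      stop("erased lobes contain no ground-truth EPVS in any subject; calibration undefined")
    fit <- train_fn(erased)
    predict_fn <- if (is.function(fit)) fit else function(s) predict(fit, s)
    tp <- fp <- fn <- numeric(length(threshold_grid))
    for (i in seq_along(subjects)) {
      prob <- predict_fn(erased[[i]])$prob$grid[erased[[i]]$erased]
      truth <- subjects[[i]]$labels$grid[erased[[i]]$erased]
      for (k in seq_along(threshold_grid)) {
        pred <- prob >= threshold_grid[k]
        tp[k] <- tp[k] + sum(pred & truth)
        fp[k] <- fp[k] + sum(pred & !truth)
        fn[k] <- fn[k] + sum(!pred & truth)
      }
    }
    d <- ifelse(2 * tp + fp + fn == 0, 1, 2 * tp / (2 * tp + fp + fn))
    opts[r] <- threshold_grid[which.max(d)]   # first max = lowest threshold
  }
  structure(mean(opts), per_repeat = opts)
}
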