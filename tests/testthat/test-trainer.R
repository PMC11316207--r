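# a tiny, fast subject for optimization-path tests: small grid, few channels
tiny_subject <- function(id = "T1", seed = 5, empty_labels = FALSE,
                         n_channels = 19) {
  set.seed(seed)
  dims <- c(16L, 16L, 8L)
  geom <- voxel_geometry()
  g <- array(FALSE, dims)
  if (!empty_labels) {
    g[2:15, 8, 4] <- TRUE        # spans all five atlas slabs
    g[10, 3:7, 5] <- TRUE
  }
  img <- array(rnorm(prod(dims)), dims) + 5 * g
  data <- cbind(as.vector(img),
                matrix(rnorm(prod(dims) * (n_channels - 1)), prod(dims)))
  data[, 2] <- as.vector(g) * 3 + rnorm(prod(dims), sd = 0.3)
  wm <- array(TRUE, dims)
  slab <- pmin(5L, 1L + (seq_len(dims[1]) - 1L) %/% 3L)
  atlas <- epvs_atlas(array(rep(slab, times = prod(dims[2:3])), dims), geom)
  list(id = id,
       inputs = epvseg:::new_stack(data, paste0("c", 1:n_channels), dims, geom),
       labels = epvs_mask(g, geom),
       wm = epvs_mask(wm, geom),
       atlas = atlas,
       gt_labels = epvs_labels(array(as.integer(g), dims), geom))
}

test_that("patch sampling draws centres uniformly inside the WM mask", {
  s <- tiny_subject()
  s$wm$grid[, 1:8, ] <- FALSE       # constrain WM to half the volume
  set.seed(71)
  centers <- t(replicate(300, sample_patch(s, c(8, 8, 8))$center))
  ok <- s$wm$grid[centers]
  expect_true(all(ok))
  # same seed -> identical sequence
  set.seed(71)
  centers2 <- t(replicate(300, sample_patch(s, c(8, 8, 8))$center))
  expect_identical(centers, centers2)
  # chi-square uniformity over the WM split into 8 octant-style cells
  set.seed(72)
  n <- 1e4
  wmidx <- which(s$wm$grid)
  draws <- integer(n)
  for (i in seq_len(n)) {
    p <- sample_patch(s, c(8, 8, 8))$center
    draws[i] <- 1L + (p[1] > 8) + 2L * (p[2] > 12) + 4L * (p[3] > 4)
  }
  cell <- arrayInd(wmidx, dim(s$wm$grid))
  expected <- tabulate(1L + (cell[, 1] > 8) + 2L * (cell[, 2] > 12) +
                         4L * (cell[, 3] > 4), 8)
  observed <- tabulate(draws, 8)
  keep <- expected > 0
  ct <- suppressWarnings(
    chisq.test(observed[keep], p = expected[keep] / sum(expected)))
  expect_gt(ct$p.value, 0.01)
  # patch geometry and label alignment
  set.seed(73)
  p <- sample_patch(s, c(8, 8, 8))
  expect_equal(attr(p$x, "dims"), c(8L, 8L, 8L))
  expect_equal(length(p$y), 8^3)
  expect_error(sample_patch(list(wm = epvs_mask(array(FALSE, c(4, 4, 4)),
                                                voxel_geometry())),
                            c(8, 8, 8)), "empty")
})

test_that("member training records history, stops early on the best DSC, and is seeded", {
  subs <- list(tiny_subject("T1", 5), tiny_subject("T2", 6))
  val <- tiny_subject("V", 7)
  cfg <- network_config(in_channels = 19, base_channels = 4,
                        convs_per_level = 1)
  tc <- training_config(epochs = 4, batches_per_epoch = 3, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 99, val_every = 1,
                        val_overlap = 0)
  mb <- train_member(subs, val, cfg, tc)
  expect_s3_class(mb, "epvs_member")
  expect_equal(nrow(mb$history), 4)
  expect_equal(mb$best_validation_dsc, max(mb$history$val_dsc))
  expect_equal(mb$best_epoch,
               mb$history$epoch[which.max(mb$history$val_dsc)])
  expect_true(mb$best_validation_dsc >= 0 && mb$best_validation_dsc <= 1)
  # identical seed -> identical trajectory and weights
  mb2 <- train_member(subs, val, cfg, tc)
  expect_equal(mb2$history, mb$history)
  expect_equal(mb2$pars, mb$pars)
  expect_error(train_member(subs, subs[[1]], cfg, tc), "also appears")
})

test_that("training on empty labels does not hallucinate foreground", {
  # With all-empty labels the F-beta numerator reduces to the epsilon
  # stabilizer, so gradients are tiny (order eps / sum(yhat)^2): the
  # honest check is that empty-label training never grows the foreground,
  # not that it reaches zero in a handful of steps.
  subs <- list(tiny_subject("T1", 5, empty_labels = TRUE),
               tiny_subject("T2", 6, empty_labels = TRUE))
  val <- tiny_subject("V", 7, empty_labels = TRUE)
  cfg <- network_config(in_channels = 19, base_channels = 4,
                        convs_per_level = 1)
  tc <- training_config(epochs = 6, batches_per_epoch = 4, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 3, val_every = 2,
                        val_overlap = 0)
  init <- build_model(cfg, seed = tc$seed)
  p0 <- predict_volume(init, val$inputs, c(16, 16, 8), 0)
  mb <- train_member(subs, val, cfg, tc)
  m <- epvseg:::member_model(mb)
  prob <- predict_volume(m, val$inputs, c(16, 16, 8), 0)
  expect_lte(sum(prob$grid >= 0.5), 1.25 * sum(p0$grid >= 0.5) + 50)
  expect_true(all(mb$history$val_dsc %in% c(0, 1)) ||
                all(is.finite(mb$history$val_loss)))
})

test_that("LOOCV builds one member per subject with deterministic holdouts", {
  subs <- list(tiny_subject("S3", 5), tiny_subject("S1", 6),
               tiny_subject("S2", 7))
  cfg <- network_config(in_channels = 19, base_channels = 3,
                        convs_per_level = 1)
  tc <- training_config(epochs = 2, batches_per_epoch = 2, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 13, val_every = 1,
                        val_overlap = 0)
  ens <- train_ensemble_loocv(subs, cfg, tc, threshold = 0.2)
  expect_s3_class(ens, "epvs_ensemble")
  expect_length(ens$members, 3)
  expect_equal(vapply(ens$members, `[[`, "", "held_out"),
               c("S1", "S2", "S3"))   # ordered by id, each exactly once
  expect_error(train_ensemble_loocv(subs[1], cfg, tc), "at least 2")
  expect_error(train_ensemble_loocv(subs, cfg, tc, threshold = 0), "threshold")
})

test_that("ensemble prediction is the member mean, thresholded", {
  s <- tiny_subject("S1", 8)
  cfg <- network_config(in_channels = 19, base_channels = 3,
                        convs_per_level = 1)
  tc <- training_config(epochs = 1, batches_per_epoch = 1, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 31, val_every = 1,
                        val_overlap = 0)
  mb <- train_member(list(tiny_subject("T", 9)), s, cfg, tc)
  mk <- function(thr) structure(list(members = list(mb, mb), threshold = thr,
                                     net_config = cfg, train_config = tc),
                                class = "epvs_ensemble")
  single <- predict_volume(epvseg:::member_model(mb), s$inputs,
                           c(16, 16, 8), 0.5)
  pr <- predict(mk(0.2), s, patch_size = c(16, 16, 8))
  # identical members -> ensemble map equals the single-member map
  expect_equal(pr$prob$grid, single$grid, tolerance = 1e-12)
  expect_equal(pr$mask$grid, pr$prob$grid >= 0.2, ignore_attr = TRUE)
  # threshold extremes
  lo <- predict(mk(1e-9), s, patch_size = c(16, 16, 8))
  expect_true(all(lo$mask$grid))
  hi <- predict(mk(1 - 1e-12), s, patch_size = c(16, 16, 8))
  expect_equal(sum(hi$mask$grid), sum(pr$prob$grid >= 1 - 1e-12))
})

test_that("threshold calibration averages grid optima and handles degenerate cases", {
  subs <- lapply(1:3, function(i) tiny_subject(paste0("S", i), 40 + i))
  # perfect-oracle predictor: probability equals the original ground truth
  truth <- lapply(subs, function(s) s$labels)
  ids <- vapply(subs, `[[`, "", "id")
  oracle <- function(subject) {
    i <- match(subject$id, ids)
    list(prob = epvs_volume(truth[[i]]$grid * 1, subject$inputs$geometry))
  }
  thr <- calibrate_threshold(subs, n_repeats = 3, seed = 5,
                             train_fn = function(ss) oracle)
  # with a 0/1 oracle every grid threshold is optimal; ties -> lowest (0.05)
  expect_equal(as.numeric(thr), 0.05)
  expect_length(attr(thr, "per_repeat"), 3)
  expect_true(all(attr(thr, "per_repeat") %in% seq(0.05, 0.95, 0.05)))
  # no ground truth anywhere in the erased lobes -> calibration undefined
  empt <- lapply(1:3, function(i)
    tiny_subject(paste0("S", i), 50 + i, empty_labels = TRUE))
  expect_error(calibrate_threshold(empt, n_repeats = 1, seed = 5,
                                   train_fn = function(ss) oracle),
               "no ground-truth")
})

test_that("identical seeds give identical ensemble masks end to end", {
  subs <- list(tiny_subject("A", 81), tiny_subject("B", 82))
  cfg <- network_config(in_channels = 19, base_channels = 3,
                        convs_per_level = 1)
  tc <- training_config(epochs = 2, batches_per_epoch = 2, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 55, val_every = 1,
                        val_overlap = 0)
  e1 <- train_ensemble_loocv(subs, cfg, tc)
  e2 <- train_ensemble_loocv(subs, cfg, tc)
  p1 <- predict(e1, subs[[1]], patch_size = c(16, 16, 8))
  p2 <- predict(e2, subs[[1]], patch_size = c(16, 16, 8))
  expect_identical(p1$mask$grid, p2$mask$grid)
  expect_identical(p1$prob$grid, p2$prob$grid)
})
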