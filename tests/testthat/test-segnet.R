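test_that("F-beta loss reproduces its closed forms", {
  # perfect binary prediction with at least one positive
  y <- c(1, 0, 1, 0)
  expect_equal(fbeta_loss(y, y, 10), 0)
  expect_equal(fbeta_loss(y, y, 0.1), 0)
  # all-empty case: 1 - eps/eps = 0
  expect_equal(fbeta_loss(c(0, 0), c(0, 0), 1), 0)
  # worked example: y = (1,0), yhat = (.5,.5), beta = 1
  expect_equal(fbeta_loss(c(1, 0), c(0.5, 0.5), 1),
               1 - (2 * 0.5 + 1e-3) / (1 + 1 + 1e-3), tolerance = 1e-12)
  expect_equal(fbeta_loss(c(1, 0), c(0.5, 0.5), 1), 0.4997501,
               tolerance = 1e-6)
  expect_error(fbeta_loss(c(1, 0), c(0.5), 1), "shape")
  expect_error(fbeta_loss(y, y, -1), "positive")
})

test_that("F-beta loss lies in [0,1) and vanishes iff the balance identity holds", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(2:64, 1)
    y <- as.numeric(runif(n) < 0.3)
    yhat <- runif(n)
    beta <- exp(runif(1, log(0.05), log(20)))
    l <- fbeta_loss(y, yhat, beta)
    expect_gte(l, 0)
    expect_lt(l, 1)
    # zero iff (1+beta) sum(y yhat) = beta sum(y) + sum(yhat)
    bal <- (1 + beta) * sum(y * yhat) - (beta * sum(y) + sum(yhat))
    expect_equal(l == 0, abs(bal) < 1e-12)
  }
})

test_that("F-beta gradient matches central finite differences within 1e-4", {
  set.seed(11)
  for (beta in c(10, 0.1, 1)) {
    n <- 40
    y <- as.numeric(runif(n) < 0.3)
    yhat <- runif(n, 0.05, 0.95)
    g <- epvseg:::fbeta_grad(y, yhat, beta)
    h <- 1e-6
    for (i in sample(n, 8)) {
      yp <- yhat; yp[i] <- yp[i] + h
      ym <- yhat; ym[i] <- ym[i] - h
      gn <- (fbeta_loss(y, yp, beta) - fbeta_loss(y, ym, beta)) / (2 * h)
      expect_equal(g[i], gn, tolerance = 1e-4)
    }
  }
})

test_that("total loss sums the three heads, is bounded, and is head-symmetric", {
  set.seed(12)
  cfg <- network_config()
  y <- as.numeric(runif(30) < 0.4)
  a <- runif(30); b <- runif(30); cc <- runif(30)
  expect_equal(total_loss(y, y, y, y, cfg), 0)
  l <- total_loss(y, a, b, cc, cfg)
  expect_gte(l, 0)
  expect_lt(l, 3)
  # swapping the two stage-1 heads together with their betas is a no-op
  cfg2 <- cfg; cfg2$betas <- c(0.1, 10, 1)
  expect_equal(total_loss(y, b, a, cc, cfg2), l)
})

test_that("network configuration validates and counts parameters sensibly", {
  expect_error(network_config(betas = c(-1, 0.1, 1)), "positive")
  expect_error(network_config(dropconnect_p = 1), "dropconnect")
  m8 <- build_model(network_config(base_channels = 8, convs_per_level = 1),
                    seed = 1)
  m16 <- build_model(network_config(base_channels = 16, convs_per_level = 1),
                     seed = 1)
  expect_gt(m16$n_parameters, m8$n_parameters)
  # default configuration lands at the ~5e6 order of magnitude
  mfull <- build_model(network_config(), seed = 1)
  expect_gt(mfull$n_parameters, 1e6)
  expect_lt(mfull$n_parameters, 5e7)
})

test_that("forward pass is deterministic at inference and shape-preserving", {
  cfg <- network_config(in_channels = 6, base_channels = 4,
                        convs_per_level = 1)
  m <- build_model(cfg, seed = 5)
  x <- matrix(rnorm(8 * 8 * 8 * 6), 8 * 8 * 8, 6)
  attr(x, "dims") <- c(8L, 8L, 8L)
  f1 <- epvseg:::forward_triple(m, x)
  f2 <- epvseg:::forward_triple(m, x)
  expect_identical(as.numeric(f1$pC), as.numeric(f2$pC))
  for (h in c("pA", "pB", "pC")) {
    expect_equal(nrow(f1[[h]]), 8 * 8 * 8)
    expect_true(all(f1[[h]] >= 0 & f1[[h]] <= 1))
  }
  expect_error(epvseg:::forward_triple(m, x[1:100, ]), "dims")
  expect_error(epvseg:::forward_triple(m, x[, 1:3]), "channels")
})

test_that("full-network gradients match finite differences (double precision)", {
  withr::local_options(epvseg.precision = "double")
  cfg <- network_config(in_channels = 4, base_channels = 3,
                        convs_per_level = 1, dropconnect_p = 0)
  m <- build_model(cfg, seed = 7)
  nv <- 8 * 8 * 8
  set.seed(7)
  x <- matrix(rnorm(nv * 4), nv, 4)
  attr(x, "dims") <- c(8L, 8L, 8L)
  y <- as.numeric(runif(nv) < 0.05)
  fw <- epvseg:::forward_triple(m, x, training = TRUE)
  seeds <- list()
  for (hb in list(c("pA", 10), c("pB", 0.1), c("pC", 1))) {
    h <- fw[[hb[1]]]
    seeds[[as.character(attr(h, "id"))]] <-
      matrix(epvseg:::fbeta_grad(y, h, as.numeric(hb[2])))
  }
  pg <- epvseg:::backprop(fw$tape, seeds)
  hstep <- 1e-5
  for (nm in sample(names(pg), 6)) {
    w <- m$pars[[nm]]
    i <- sample(length(w), 1)
    for (s in c(1, -1)) {
      wi <- w; wi[i] <- wi[i] + s * hstep
      m$pars[[nm]] <- wi
      f <- epvseg:::forward_triple(m, x, training = TRUE)
      l <- total_loss(y, f$pA, f$pB, f$pC, cfg)
      if (s == 1) lp <- l else lm <- l
    }
    m$pars[[nm]] <- w
    gn <- (lp - lm) / (2 * hstep)
    # combined absolute/relative band: a perturbation can cross a
    # ReLU/argmax kink, where one-sided curvature inflates the FD value
    expect_lt(abs(pg[[nm]][i] - gn), 1e-5 + 0.02 * abs(gn))
  }
})

test_that("whole-volume inference averages windows, stays in [0,1], and reflect-pads", {
  cfg <- network_config(in_channels = 3, base_channels = 2,
                        convs_per_level = 1)
  m <- build_model(cfg, seed = 2)
  geom <- voxel_geometry()
  mk_inputs <- function(dims) {
    epvseg:::new_stack(matrix(rnorm(prod(dims) * 3), prod(dims), 3),
                       c("a", "b", "c"), dims, geom)
  }
  st <- mk_inputs(c(20L, 20L, 12L))
  p1 <- predict_volume(m, st, c(8, 8, 8), overlap_fraction = 0)
  p2 <- predict_volume(m, st, c(8, 8, 8), overlap_fraction = 0.5)
  expect_equal(dim(p1$grid), c(20L, 20L, 12L))
  expect_true(all(p1$grid >= 0 & p1$grid <= 1))
  expect_true(all(p2$grid >= 0 & p2$grid <= 1))
  # a constant-output model (all-zero weights -> sigmoid(0)) is tiling-invariant
  for (nm in ls(m$pars)) m$pars[[nm]] <- m$pars[[nm]] * 0
  q1 <- predict_volume(m, st, c(8, 8, 8), overlap_fraction = 0)
  q2 <- predict_volume(m, st, c(8, 8, 8), overlap_fraction = 0.5)
  expect_equal(unique(as.vector(q1$grid)), 0.5)
  expect_equal(q1$grid, q2$grid)
  # volume smaller than the patch: reflect-pad, predict, crop
  sm <- mk_inputs(c(6L, 6L, 6L))
  ps <- predict_volume(m, sm, c(8, 8, 8))
  expect_equal(dim(ps$grid), c(6L, 6L, 6L))
  expect_error(predict_volume(m, st, c(9, 8, 8)), "divisible")
})

test_that("the default pipeline input assembly has 19 channels", {
  s <- small_subject()
  expect_equal(ncol(s$inputs$data), 19)
  expect_equal(s$inputs$names[1], "image")
  expect_equal(s$inputs$names[14], "wm")
  expect_equal(s$inputs$names[15:19],
               c("frontal", "parietal", "temporal", "occipital",
                 "basal_ganglia"))
  expect_equal(network_config()$in_channels, 19L)
})

test_that("a few optimization steps on a tube phantom decrease the loss", {
  ph <- small_phantom()
  sub <- small_subject()
  cfg <- network_config(in_channels = 19, base_channels = 4,
                        convs_per_level = 1)
  tc <- training_config(epochs = 3, batches_per_epoch = 4, batch_size = 1,
                        patch_size = c(16, 16, 8), seed = 21, val_every = 1,
                        val_overlap = 0)
  mb <- train_member(list(sub), modifyList(sub, list(id = "V")),
                     cfg, tc)
  expect_lt(mb$history$train_loss[nrow(mb$history)],
            mb$history$train_loss[1])
  expect_true(all(mb$history$val_dsc >= 0 & mb$history$val_dsc <= 1))
})
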