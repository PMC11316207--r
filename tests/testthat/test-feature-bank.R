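test_that("map counts follow the per-filter contract and the bank formula", {
  v <- tube_volume(c(16, 16, 8))
  expect_equal(n_features(steerable_features(v, 1)), 19)
  expect_equal(n_features(frangi_features(v, 1)), 5)
  expect_equal(n_features(oof_features(v, 1)), 5)
  expect_equal(feature_count(filter_bank_config()), 354)
  expect_equal(feature_count(filter_bank_config(use_tophat_branch = FALSE)),
               177)
  cfg38 <- filter_bank_config(sf_sigmas_mm = 1, ff_sigmas_mm = numeric(),
                              oof_radii_mm = numeric())
  expect_equal(feature_count(cfg38), 38)
  st <- assemble_feature_stack(v, cfg38)
  expect_equal(n_features(st), 38)

  # counting formula holds for arbitrary random configurations
  set.seed(5)
  for (i in 1:8) {
    ns <- sample(0:4, 3, replace = TRUE)
    th <- sample(c(TRUE, FALSE), 1)
    cfg <- filter_bank_config(
      sf_sigmas_mm = sort(runif(ns[1], 0.5, 3)),
      ff_sigmas_mm = sort(runif(ns[2], 0.4, 3)),
      oof_radii_mm = sort(runif(ns[3], 0.6, 3)),
      use_tophat_branch = th)
    expect_equal(feature_count(cfg),
                 (1 + th) * (19 * ns[1] + 5 * ns[2] + 5 * ns[3]))
  }
})

test_that("filters vanish on a constant image", {
  flat <- epvs_volume(array(4, c(12, 12, 8)), voxel_geometry())
  sf <- steerable_features(flat, 1)
  expect_equal(max(abs(sf$data[, 1] - 4)), 0, tolerance = 1e-10)
  expect_lt(max(abs(sf$data[, -1])), 1e-10)
  expect_lt(max(abs(frangi_features(flat, 1)$data)), 1e-10)
  expect_lt(max(abs(oof_features(flat, 1)$data)), 1e-10)
})

test_that("steerable derivatives are exact on a linear ramp", {
  geom <- voxel_geometry(c(0.6, 0.6, 1.5))
  d <- c(20L, 20L, 12L)
  a <- 1.7
  ramp <- array(rep((seq_len(d[1]) - 1) * 0.6 * a, times = d[2] * d[3]), d)
  sf <- steerable_features(epvs_volume(ramp, geom), 1)
  ors <- steerable_orientations()
  interior <- array(FALSE, d)
  interior[8:13, 8:13, 5:8] <- TRUE
  for (k in 1:9) {
    d1 <- stack_map(sf, 1 + k)[interior]
    expect_equal(d1, rep(a * ors[k, 1], length(d1)), tolerance = 1e-6)
    d2 <- stack_map(sf, 10 + k)[interior]
    expect_lt(max(abs(d2)), 1e-6)
  }
})

test_that("steerable derivatives agree with finite differences of the smoothed image", {
  v <- tube_volume(c(24, 24, 12), axis = 2, radius_mm = 2)
  sf <- steerable_features(v, 1.8)
  G <- stack_map(sf, 1)
  dx <- v$geometry$spacing_mm[1]
  fd <- (G[3:24, , ] - G[1:22, , ]) / (2 * dx)
  got <- stack_map(sf, 2)[2:23, , ]      # orientation 1 = +x
  rms <- sqrt(mean((got - fd)^2)) / sqrt(mean(fd^2))
  expect_lt(rms, 0.02)
})

test_that("Frangi vesselness lights up on a bright tube and obeys the sign gate", {
  v <- tube_volume(c(24, 24, 12), axis = 1, radius_mm = 1.0, contrast = 3)
  fr <- frangi_features(v, 1.0)
  V <- stack_map(fr, "vesselness")
  on_axis <- V[6:19, 12, 6]
  off <- V[, , c(1:3, 10:12)]
  expect_gt(min(on_axis), quantile(off, 0.99))
  # V = 0 wherever lambda2 > 0 or lambda3 > 0
  l2 <- fr$data[, 2]; l3 <- fr$data[, 3]
  expect_true(all(fr$data[l2 > 0 | l3 > 0, 4] == 0))
})

test_that("Frangi eigenvalue maps match a per-voxel eigen() oracle", {
  set.seed(8)
  geom <- voxel_geometry()
  v <- epvs_volume(array(rnorm(14 * 12 * 10), c(14, 12, 10)), geom)
  sg <- 1.1
  fr <- frangi_features(v, sg)
  H <- epvseg:::gauss_hessian(v$grid, geom$spacing_mm, sg)
  idx <- sample(length(v$grid), 200)
  for (i in idx) {
    M <- sg^2 * matrix(c(H$hxx[i], H$hxy[i], H$hxz[i],
                         H$hxy[i], H$hyy[i], H$hyz[i],
                         H$hxz[i], H$hyz[i], H$hzz[i]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    got <- unname(sort(fr$data[i, 1:3]))   # algebraic ascending
    expect_equal(got, sort(ev), tolerance = 1e-6)
  }
})

test_that("OOF matches an independent spherical-flux oracle on a small grid", {
  set.seed(3)
  geom <- voxel_geometry()
  d <- c(10L, 10L, 8L)
  v <- epvs_volume(array(rnorm(prod(d)), d), geom)
  r <- 1.5
  of <- oof_features(v, r, n_points = 40)
  # independent R implementation: same definition, written from scratch
  sp <- geom$spacing_mm
  gr <- epvseg:::gauss_gradient(v$grid, sp, min(sp))
  pts <- epvseg:::fibonacci_sphere(40)
  tri <- function(G, p) {
    p <- pmin(pmax(p, c(0, 0, 0)), d - 1)
    f0 <- floor(p); fr_ <- p - f0
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      q <- pmin(f0 + c(cx, cy, cz), d - 1)
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr_, 1 - fr_))
      acc <- acc + w * G[q[1] + 1, q[2] + 1, q[3] + 1]
    }
    acc
  }
  for (trial in 1:25) {
    vox <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    Q <- matrix(0, 3, 3)
    for (k in 1:40) {
      nrm <- pts[k, ]
      p <- (vox - 1) + r * nrm / sp
      g <- c(tri(gr$gx, p), tri(gr$gy, p), tri(gr$gz, p))
      Q <- Q + (outer(g, nrm) + outer(nrm, g)) / 2
    }
    Q <- Q / 40
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    i <- vox[1] + d[1] * (vox[2] - 1 + d[2] * (vox[3] - 1))
    expect_equal(unname(sort(of$data[i, 1:3])), sort(ev), tolerance = 1e-6)
  }
  # bright tube: tube measure maximal on axis, near zero in background
  tv <- tube_volume(c(20, 20, 10), axis = 1, radius_mm = 1.0, contrast = 3)
  ot <- oof_features(tv, 1.0)
  tm <- stack_map(ot, "tube")
  expect_gt(min(tm[6:15, 10, 5]), quantile(tm[, , c(1, 10)], 0.99))
})

test_that("responses are consistent under an axis-aligned 90-degree rotation", {
  v <- tube_volume(c(20, 20, 10), axis = 1, radius_mm = 0.9, contrast = 3)
  rot <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, ]  # 90 deg about z
  vr <- epvs_volume(rot(v$grid), v$geometry)
  V1 <- rot(stack_map(frangi_features(v, 1), "vesselness"))
  V2 <- stack_map(frangi_features(vr, 1), "vesselness")
  expect_equal(dim(V2), dim(V1))
  expect_equal(V2, V1, tolerance = 1e-8)
})

test_that("stack assembly is deterministic and ordered branch > family > scale", {
  v <- tube_volume(c(16, 16, 8))
  cfg <- filter_bank_config(sf_sigmas_mm = 1, ff_sigmas_mm = 1.5,
                            oof_radii_mm = 1.5)
  st <- assemble_feature_stack(v, cfg)
  expect_equal(n_features(st), 2 * (19 + 5 + 5))
  expect_match(st$names[1], "^raw\\.sf")
  expect_match(st$names[20], "^raw\\.ff")
  expect_match(st$names[25], "^raw\\.oof")
  expect_match(st$names[30], "^tophat\\.sf")
  st2 <- assemble_feature_stack(v, cfg)
  expect_identical(st$data, st2$data)
})
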