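test_that("connectivity semantics: corner-touching voxels", {
  geom <- voxel_geometry()
  g <- array(FALSE, c(4, 4, 4))
  g[2, 2, 2] <- TRUE
  g[3, 3, 3] <- TRUE             # shares only a corner
  m <- epvs_mask(g, geom)
  expect_equal(nrow(extract_instances(m, connectivity = 26)), 1)
  expect_equal(nrow(extract_instances(m, connectivity = 6)), 2)
  empty <- extract_instances(epvs_mask(array(FALSE, c(4, 4, 4)), geom))
  expect_equal(nrow(empty), 0)
})

test_that("instance labelling matches a flood-fill oracle on random sparse masks", {
  set.seed(31)
  geom <- voxel_geometry()
  for (trial in 1:4) {
    d <- sample(8:14, 3, replace = TRUE)
    g <- array(runif(prod(d)) < 0.12, d)
    m <- epvs_mask(g, geom)
    for (conn in c(26L, 6L)) {
      inst <- extract_instances(m, connectivity = conn)
      oracle <- cc_oracle(g, conn)
      expect_equal(nrow(inst), max(oracle))
      # identical partition: components as voxel sets
      lab <- attr(inst, "labels")$grid
      part <- function(l) unname(split(which(l > 0), l[l > 0]))
      expect_setequal(lapply(part(lab), sort), lapply(part(oracle), sort))
    }
  }
})

test_that("instance volumes and min_voxels filtering are correct", {
  geom <- voxel_geometry()
  g <- array(FALSE, c(8, 8, 4))
  g[2:4, 2, 2] <- TRUE           # 3 voxels
  g[7, 7, 3] <- TRUE             # singleton
  m <- epvs_mask(g, geom)
  inst <- extract_instances(m)
  expect_equal(sort(inst$volume_mm3), sort(c(3, 1) * 0.54))
  expect_equal(nrow(extract_instances(m, min_voxels = 2)), 1)
})

test_that("regional summary applies the majority rule with smallest-code ties", {
  geom <- voxel_geometry()
  d <- c(12, 8, 4)
  atlas <- epvs_atlas(array(0L, d), geom)
  atlas$grid[1:6, , ] <- 1L      # frontal
  atlas$grid[7:12, , ] <- 2L     # parietal
  g <- array(FALSE, d)
  g[4:9, 4, 2] <- TRUE           # 3 frontal + 3 parietal voxels: tie -> frontal
  g[10:12, 6, 3] <- TRUE         # fully parietal
  inst <- extract_instances(epvs_mask(g, geom))
  s <- summarize_epvs(inst, atlas)
  expect_equal(unname(s$counts["frontal"]), 1L)
  expect_equal(unname(s$counts["parietal"]), 1L)
  expect_equal(s$cerebrum_total, 2L)
  # 6 frontal + 4 parietal voxels -> frontal
  g2 <- array(FALSE, d)
  g2[1:6, 2, 1] <- TRUE
  g2[7:10, 2, 1] <- TRUE
  s2 <- summarize_epvs(extract_instances(epvs_mask(g2, geom)), atlas)
  expect_equal(unname(s2$counts["frontal"]), 1L)
  expect_equal(unname(s2$counts["parietal"]), 0L)
})

test_that("density arithmetic: 37 instances in 100 cm^3 give 0.37 per cm^3", {
  geom <- voxel_geometry(c(1, 1, 1))
  d <- c(100L, 100L, 20L)
  atlas_grid <- array(0L, d)
  atlas_grid[, , 1:10] <- 5L     # basal ganglia: 1e5 mm^3 = 100 cm^3
  atlas <- epvs_atlas(atlas_grid, geom)
  g <- array(FALSE, d)
  xs <- seq(2, 98, length.out = 37)
  for (k in seq_along(xs)) g[round(xs[k]), 2 * k, 3] <- TRUE
  s <- summarize_epvs(extract_instances(epvs_mask(g, geom)), atlas)
  expect_equal(unname(s$counts["basal_ganglia"]), 37L)
  expect_equal(unname(s$densities["basal_ganglia"]), 0.37)
})

test_that("phantom ground truth summarizes to the generator bookkeeping", {
  ph <- small_phantom()
  inst <- extract_instances(epvs_mask(ph$gt_labels$grid > 0,
                                      ph$image$geometry))
  expect_equal(nrow(inst), nrow(ph$instances))
  s <- summarize_epvs(inst, ph$atlas)
  book <- table(factor(ph$instances$region,
                       levels = names(epvs_regions())[-1]))
  expect_equal(unname(s$counts), as.integer(book))
  # conservation: regional counts + unassigned = total
  expect_equal(sum(s$counts) + s$unassigned, s$cerebrum_total)
})

test_that("binning follows the stated rule (worked edges) and the oracle", {
  # counts engineered so nearest-rank p50 = 10 and p75 = 22
  counts <- c(2, 5, 7, 10, 14, 22, 26, 30)
  sch <- fit_binning(counts, "lobar")
  expect_equal(sch$p50, 10)
  expect_equal(sch$p75, 22)
  expect_equal(sch$edges, c(14, 18, 22))
  expect_equal(apply_binning(15, sch), 12L)   # level "p50 + 2"
  expect_equal(apply_binning(10, sch), 10L)   # identity region boundary
  expect_equal(apply_binning(0, sch), 0L)
  expect_equal(apply_binning(14, sch), 11L)
  expect_equal(apply_binning(23, sch), 14L)   # top level p50 + 4

  # cerebrum scheme has 8 levels: 4 below-median + 3 interval + 1 top
  schc <- fit_binning(counts, "cerebrum")
  lv <- apply_binning(c(0, 3, 5, 8, 10, 11, 22, 23, 100), schc)
  expect_true(all(lv >= 1 & lv <= 8))
  expect_equal(apply_binning(10, schc), 4L)
  expect_equal(apply_binning(11, schc), 5L)
  expect_equal(apply_binning(23, schc), 8L)

  # randomized agreement with an independent re-implementation
  set.seed(41)
  for (trial in 1:10) {
    cs <- sort(rpois(sample(6:30, 1), lambda = sample(5:40, 1)))
    for (kind in c("lobar", "cerebrum")) {
      sch <- suppressWarnings(fit_binning(cs, kind))
      probe <- 0:max(cs + 5)
      expect_equal(suppressWarnings(apply_binning(probe, sch)),
                   binning_oracle(probe, cs, kind))
    }
  }
})

test_that("binning is monotone, collapses degenerate spreads, and validates input", {
  counts <- c(3, 9, 15, 40, 2, 7)
  sch <- fit_binning(counts, "lobar")
  x <- sort(sample(0:60, 30, replace = TRUE))
  expect_true(all(diff(apply_binning(x, sch)) >= 0))
  expect_warning(fit_binning(rep(5L, 6), "lobar"), "collapsed")
  sch0 <- suppressWarnings(fit_binning(rep(5L, 6), "lobar"))
  expect_equal(apply_binning(c(5, 6, 100), sch0), c(5L, 6L, 6L))
  expect_error(fit_binning(c(1, 2), "lobar"), "at least 4")
  expect_error(fit_binning(c(-1, 2, 3, 4), "lobar"), "non-negative")
})

test_that("the subject table carries counts, densities and bins per region", {
  ph <- small_phantom()
  inst <- extract_instances(epvs_mask(ph$gt_labels$grid > 0,
                                      ph$image$geometry))
  s <- summarize_epvs(inst, ph$atlas)
  sums <- list(P01 = s, P02 = s, P03 = s, P04 = s)
  tab <- suppressWarnings(epvs_subject_table(sums))  # degenerate spread
  expect_equal(nrow(tab), 4)
  expect_true(all(c("count_frontal", "density_basal_ganglia",
                    "bin_cerebrum", "count_cerebrum") %in% names(tab)))
})
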