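#' Configuration for synthetic hemisphere phantoms
#'
#' The generator emulates a T2-weighted ex vivo hemisphere at
#' 0.6 x 0.6 x 1.5 mm: an ellipsoidal half-dome split into four angular
#' pseudo-lobes plus a deep basal-ganglia blob, a white-matter interior,
#' hyperintense tortuous tubes (the EPVS) anchored in white matter, a
#' smooth multiplicative bias field, optional bright distractor blobs,
#' and Rician (magnitude-MR) or Gaussian noise.
#'
#' @param shape grid size in voxels (default 96 x 96 x 48).
#' @param spacing_mm voxel spacing (default `c(0.6, 0.6, 1.5)`).
#' @param region_counts named integer vector of EPVS counts per region
#'   (frontal, parietal, temporal, occipital, basal_ganglia). The default
#'   places most EPVS in the frontal lobe but the highest density in the
#'   small basal-ganglia blob.
#' @param radius_range_mm tube radius range (default 0.3-1.2 mm).
#' @param length_range_mm tube length range (default 2-15 mm).
#' @param tortuosity_deg_per_mm random-walk direction change (default 10).
#' @param tissue_mean mean tissue intensity (arbitrary units).
#' @param contrast EPVS-to-tissue intensity multiplier (> 1, default 3).
#' @param bias_amplitude relative amplitude of the multiplicative bias
#'   field (default 0.1 = +/-10 percent).
#' @param noise `"rician"` (default, magnitude MR) or `"gaussian"`.
#' @param noise_sigma_frac noise sigma as a fraction of `tissue_mean`
#'   (default 0.1, i.e. SNR 10 in tissue).
#' @param n_distractors bright non-EPVS blobs (default 3).
#' @param n_small_guaranteed,n_large_guaranteed numbers of extra tubes
#'   constructed to fall below 3 mm^3 / above 12 mm^3, for exercising the
#'   size-sensitivity bins.
#' @return a `phantom_config` object.
#' @export
phantom_config <- function(shape = c(96L, 96L, 48L),
                           spacing_mm = c(0.6, 0.6, 1.5),
                           region_counts = c(frontal = 16L, parietal = 10L,
                                             temporal = 5L, occipital = 3L,
                                             basal_ganglia = 12L),
                           radius_range_mm = c(0.3, 1.2),
                           length_range_mm = c(2, 15),
                           tortuosity_deg_per_mm = 10,
                           tissue_mean = 100, contrast = 3,
                           bias_amplitude = 0.1,
                           noise = c("rician", "gaussian"),
                           noise_sigma_frac = 0.1,
                           n_distractors = 3L,
                           n_small_guaranteed = 0L,
                           n_large_guaranteed = 0L) {
  noise <- match.arg(noise)
  if (contrast <= 1) stop("contrast must exceed 1")
  if (min(radius_range_mm) < min(spacing_mm[1:2]) / 2)
    stop("tube radii must be at least half the in-plane spacing")
  if (any(region_counts < 0)) stop("region counts must be non-negative")
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 region_counts = region_counts,
                 radius_range_mm = radius_range_mm,
                 length_range_mm = length_range_mm,
                 tortuosity_deg_per_mm = tortuosity_deg_per_mm,
                 tissue_mean = tissue_mean, contrast = contrast,
                 bias_amplitude = bias_amplitude, noise = noise,
                 noise_sigma_frac = noise_sigma_frac,
                 n_distractors = as.integer(n_distractors),
                 n_small_guaranteed = as.integer(n_small_guaranteed),
                 n_large_guaranteed = as.integer(n_large_guaranteed)),
            class = "phantom_config")
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# tortuous polyline from an anchor point (mm), step 1 mm
tube_polyline <- function(anchor_mm, length_mm, tort_deg_per_mm) {
  step <- 1
  n <- max(2L, ceiling(length_mm / step) + 1L)
  dirv <- runit()
  verts <- matrix(0, n, 3)
  verts[1, ] <- anchor_mm
  sdang <- tort_deg_per_mm * pi / 180 * step
  for (i in 2:n) {
    dirv <- dirv + rnorm(3, sd = sdang)
    dirv <- dirv / sqrt(sum(dirv^2))
    verts[i, ] <- verts[i - 1, ] + step * dirv
  }
  verts
}

# voxel indices (linear) within `radius` of the polyline, restricted to a mask
rasterize_tube <- function(verts, radius_mm, shape, spacing, inside) {
  lo <- pmax(0L, as.integer(floor(apply(verts, 2, min) / spacing)) -
               as.integer(ceiling(radius_mm / spacing)) - 1L)
  hi <- pmin(shape - 1L, as.integer(ceiling(apply(verts, 2, max) / spacing)) +
               as.integer(ceiling(radius_mm / spacing)) + 1L)
  if (any(hi < lo)) return(integer())
  d <- cpp_polyline_dist(verts, lo, hi, spacing)
  box <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  sel <- d < radius_mm
  if (!any(sel)) return(integer())
  lin <- 1L + box[sel, 1] + shape[1] * (box[sel, 2] + shape[2] * box[sel, 3])
  lin[inside[lin]]
}

#' Generate one synthetic hemisphere phantom
#'
#' Seeded and fully deterministic: the same config and seed give a
#' bit-identical phantom. Tubes are rasterized by physical distance to a
#' tortuous polyline (anisotropy-aware); tubes are rejected and redrawn if
#' they would overlap an existing instance, and generation fails if the
#' requested counts cannot be placed within the retry budget.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return an `epvs_phantom`: list with `image` ([epvs_volume()]), `atlas`
#'   ([epvs_atlas()]), `wm_mask`, `hemi_mask` ([epvs_mask()]),
#'   `gt_labels` ([epvs_labels()]) and the per-instance bookkeeping table
#'   `instances` (id, region, `n_voxels`, `volume_mm3`).
#' @export
make_phantom <- function(config = phantom_config(), seed = 1L) {
  set.seed(seed)
  shape <- config$shape
  sp <- config$spacing_mm
  ext <- shape * sp
  # physical voxel-centre coordinates
  xs <- (seq_len(shape[1]) - 0.5) * sp[1]
  ys <- (seq_len(shape[2]) - 0.5) * sp[2]
  zs <- (seq_len(shape[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), shape)
  ctr <- c(ext[1] / 2, ext[2] / 2, 0)
  ax <- c(0.45 * ext[1], 0.45 * ext[2], 0.85 * ext[3])
  hemi <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
    (Z / ax[3])^2 <= 1
  margin <- 2.4
  wm <- ((X - ctr[1]) / (ax[1] - margin))^2 +
    ((Y - ctr[2]) / (ax[2] - margin))^2 +
    (Z / (ax[3] - margin))^2 <= 1 & Z >= margin
  # basal ganglia: deep central blob
  bg <- ((X - ctr[1]) / (0.3 * ax[1]))^2 + ((Y - ctr[2]) / (0.3 * ax[2]))^2 +
    ((Z - 0.4 * ax[3]) / (0.35 * ax[3]))^2 <= 1
  bg <- bg & hemi
  theta <- atan2(Y - ctr[2], X - ctr[1])
  atlas_grid <- array(0L, shape)
  atlas_grid[hemi & theta >= -pi / 4 & theta < pi / 4] <- 1L   # frontal
  atlas_grid[hemi & theta >= pi / 4 & theta < 3 * pi / 4] <- 2L # parietal
  atlas_grid[hemi & (theta >= 3 * pi / 4 | theta < -3 * pi / 4)] <- 3L # temporal
  atlas_grid[hemi & theta >= -3 * pi / 4 & theta < -pi / 4] <- 4L # occipital
  atlas_grid[bg] <- 5L

  geom <- voxel_geometry(sp)
  gt <- array(0L, shape)
  inst_region <- integer()
  region_names <- names(epvs_regions())[-1]
  hemi_lin <- as.vector(hemi)
  next_id <- 0L
  # linear-index offsets of the 26-neighbourhood (used to keep distinct
  # tubes from touching, so instance bookkeeping matches 26-connected
  # component extraction exactly)
  nb26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb26 <- nb26[rowSums(abs(nb26)) > 0, ]
  nb_off <- nb26[, 1] + shape[1] * (nb26[, 2] + shape[2] * nb26[, 3])
  touches_existing <- function(vox) {
    nb <- outer(vox, nb_off, "+")
    nb <- nb[nb >= 1 & nb <= length(gt)]
    any(gt[vox] > 0L) || any(gt[nb] > 0L)
  }
  place_tube <- function(region, rmin, rmax, lmin, lmax) {
    anchors <- which(as.vector(wm) & as.vector(atlas_grid) == region)
    if (!length(anchors)) stop("region '", region_names[region],
                               "' has no white-matter anchor voxels")
    for (attempt in 1:40) {
      a <- arrayInd(anchors[sample.int(length(anchors), 1L)], shape)[1, ]
      radius <- runif(1, rmin, rmax)
      len <- runif(1, lmin, lmax)
      verts <- tube_polyline((a - 1) * sp, len, config$tortuosity_deg_per_mm)
      vox <- rasterize_tube(verts, radius, shape, sp, hemi_lin)
      if (length(vox) == 0 || touches_existing(vox)) next
      next_id <<- next_id + 1L
      gt[vox] <<- next_id
      return(invisible(TRUE))
    }
    stop("could not place the requested EPVS without overlap (region '",
         region_names[region], "'); reduce counts or enlarge the phantom")
  }
  rr <- config$radius_range_mm; lr <- config$length_range_mm
  for (reg in 1:5) {
    k <- config$region_counts[[region_names[reg]]]
    if (is.null(k) || is.na(k)) k <- 0L
    for (i in seq_len(k)) place_tube(reg, rr[1], rr[2], lr[1], lr[2])
  }
  for (i in seq_len(config$n_small_guaranteed))
    place_tube(1L, max(0.3, rr[1]), 0.4, 2, 2.5)        # < 3 mm^3
  for (i in seq_len(config$n_large_guaranteed))
    place_tube(1L, 0.9, max(1.2, rr[2]), 10, lr[2])      # > 12 mm^3

  # image: tissue + EPVS + distractors, bias field, noise
  img <- array(0.05 * config$tissue_mean, shape)
  img[hemi] <- config$tissue_mean
  img[gt > 0L] <- config$tissue_mean * config$contrast
  for (i in seq_len(config$n_distractors)) {
    wmv <- which(as.vector(wm) & as.vector(gt) == 0L)
    c0 <- arrayInd(wmv[sample.int(length(wmv), 1L)], shape)[1, ]
    r0 <- runif(1, 0.8, 1.5)
    blob <- ((X - (c0[1] - 0.5) * sp[1]) / r0)^2 +
      ((Y - (c0[2] - 0.5) * sp[2]) / r0)^2 +
      ((Z - (c0[3] - 0.5) * sp[3]) / r0)^2 <= 1
    blob <- blob & hemi & gt == 0L
    img[blob] <- config$tissue_mean * config$contrast
  }
  if (config$bias_amplitude > 0) {
    f <- array(0, shape)
    for (k in 1:3) {
      fr <- runif(3, 0.5, 1.5); ph <- runif(3, 0, 2 * pi)
      f <- f + cos(pi * fr[1] * X / ext[1] + ph[1]) *
        cos(pi * fr[2] * Y / ext[2] + ph[2]) *
        cos(pi * fr[3] * Z / ext[3] + ph[3])
    }
    f <- f / max(abs(f))
    img <- img * (1 + config$bias_amplitude * f)
  }
  sig <- config$noise_sigma_frac * config$tissue_mean
  if (sig > 0) {
    if (config$noise == "gaussian") {
      img <- img + array(rnorm(length(img), sd = sig), shape)
    } else {
      img <- sqrt((img + array(rnorm(length(img), sd = sig), shape))^2 +
                    array(rnorm(length(img), sd = sig), shape)^2)
    }
  }
  # final instance identity: 26-connected components of the rasterized
  # tubes (a thin tube can fragment across the coarse slice spacing, and
  # this keeps the bookkeeping identical to what instance extraction sees)
  gt <- array(cpp_cc_label(gt > 0L, shape, 26L), shape)
  n_inst <- max(gt)
  sizes <- tabulate(gt, nbins = n_inst)
  inst_region <- vapply(seq_len(n_inst), function(k) {
    votes <- tabulate(atlas_grid[gt == k] + 1L, nbins = 6L)
    which.max(votes) - 1L
  }, integer(1))
  instances <- data.frame(id = seq_len(n_inst),
                          region = region_names[pmax(inst_region, 1L)],
                          region_code = inst_region,
                          n_voxels = sizes,
                          volume_mm3 = sizes * geom$voxel_volume_mm3)
  instances$region[inst_region == 0L] <- "unassigned"
  structure(list(image = epvs_volume(img, geom),
                 atlas = epvs_atlas(atlas_grid, geom),
                 wm_mask = epvs_mask(wm, geom),
                 hemi_mask = epvs_mask(hemi, geom),
                 gt_labels = epvs_labels(gt, geom),
                 instances = instances,
                 config = config, seed = seed),
            class = "epvs_phantom")
}

#' @export
print.epvs_phantom <- function(x, ...) {
  cat(sprintf("epvs_phantom %s (seed %d): %d EPVS instances, %.1f cm^3 hemisphere\n",
              paste(dim(x$image$grid), collapse = " x "), x$seed,
              nrow(x$instances),
              sum(x$hemi_mask$grid) * x$image$geometry$voxel_volume_mm3 / 1000))
  invisible(x)
}

#' Generate a phantom cohort with right-skewed EPVS burdens
#'
#' Per-subject total EPVS counts are drawn from a log-normal distribution
#' (right-skewed, as real per-participant counts are) and split across
#' regions by a multinomial with the default regional proportions; each
#' phantom's seed derives deterministically from the master seed.
#'
#' @param n_subjects number of phantoms (>= 2).
#' @param seed master seed.
#' @param base_config a [phantom_config()] used as template.
#' @param meanlog,sdlog log-normal parameters of the total count
#'   (defaults `log(40)` and 0.5).
#' @return list of `epvs_phantom` objects with ids "P01", "P02", ...
#' @export
make_cohort <- function(n_subjects, seed = 1L,
                        base_config = phantom_config(),
                        meanlog = log(40), sdlog = 0.5) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  set.seed(seed)
  totals <- pmax(4L, pmin(300L, round(rlnorm(n_subjects, meanlog, sdlog))))
  probs <- base_config$region_counts / sum(base_config$region_counts)
  seeds <- sample.int(2^30, n_subjects)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- base_config
    rc <- as.vector(stats::rmultinom(1, totals[i], probs))
    names(rc) <- names(base_config$region_counts)
    cfg$region_counts <- rc
    ph <- make_phantom(cfg, seed = seeds[i])
    ph$id <- sprintf("P%02d", i)
    out[[i]] <- ph
  }
  out
}
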