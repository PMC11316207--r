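#' Instance-labelled mask
#'
#' Integer 3D array in which voxels of the k-th connected EPVS instance
#' carry the value k (0 = background).
#'
#' @param grid 3D integer array.
#' @param geometry a [voxel_geometry()].
#' @export
epvs_labels <- function(grid, geometry = voxel_geometry()) {
  grid <- array(as.integer(grid), dim = dim(as.array(grid)))
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (any(is.na(grid)) || any(grid < 0L)) stop("labels must be non-negative")
  structure(list(grid = grid, geometry = geometry), class = "epvs_labels")
}

#' @export
print.epvs_labels <- function(x, ...) {
  cat(sprintf("epvs_labels %s: %d instances, %d foreground voxels\n",
              paste(dim(x$grid), collapse = " x "),
              length(setdiff(unique(as.vector(x$grid)), 0L)),
              sum(x$grid > 0)))
  invisible(x)
}

#' Extract EPVS instances from a binary segmentation
#'
#' Maximal connected components of the mask under the requested
#' connectivity (default 26, so thin oblique tubes do not fragment on the
#' anisotropic grid); components smaller than `min_voxels` are dropped.
#'
#' @param mask an [epvs_mask()].
#' @param connectivity 26 (default) or 6.
#' @param min_voxels minimum component size kept (default 1 keeps all).
#' @return an `epvs_instances` data frame (id, `n_voxels`, `volume_mm3`,
#'   centroid in mm) with the relabelled [epvs_labels()] in
#'   `attr(, "labels")`.
#' @export
extract_instances <- function(mask, connectivity = 26L, min_voxels = 1L) {
  stopifnot(inherits(mask, "epvs_mask"), connectivity %in% c(6L, 26L))
  dims <- dim(mask$grid)
  lab <- array(cpp_cc_label(mask$grid, dims, as.integer(connectivity)), dims)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab2 <- array(0L, dims)
  nz <- lab > 0L
  lab2[nz] <- relab[lab[nz]]
  sp <- mask$geometry$spacing_mm
  inst <- if (length(keep)) {
    cent <- t(vapply(seq_along(keep), function(k) {
      colMeans(arrayInd(which(lab2 == k), dims)) * sp
    }, numeric(3)))
    data.frame(id = seq_along(keep), n_voxels = sizes[keep],
               volume_mm3 = sizes[keep] * mask$geometry$voxel_volume_mm3,
               cx_mm = cent[, 1], cy_mm = cent[, 2], cz_mm = cent[, 3])
  } else {
    data.frame(id = integer(), n_voxels = integer(),
               volume_mm3 = numeric(), cx_mm = numeric(),
               cy_mm = numeric(), cz_mm = numeric())
  }
  structure(inst, labels = epvs_labels(lab2, mask$geometry),
            class = c("epvs_instances", "data.frame"))
}

#' Regional counts and densities of EPVS instances
#'
#' Assigns each instance to a region by majority voxel label (ties broken
#' toward the smallest label code) and reports per-region counts,
#' densities (count per cm^3 of region tissue) and the cerebrum total -
#' all instances in the volume, including any in unlabelled tissue.
#'
#' @param instances an `epvs_instances` object (see [extract_instances()]).
#' @param atlas an [epvs_atlas()] aligned with the segmentation.
#' @return an `epvs_summary`: list with `counts`, `densities`,
#'   `region_volumes_cm3`, `cerebrum_total`, `unassigned`, and the
#'   per-instance `table`.
#' @export
summarize_epvs <- function(instances, atlas) {
  labels <- attr(instances, "labels")
  if (!identical(dim(labels$grid), dim(atlas$grid)))
    stop("atlas not aligned with the segmentation")
  region_names <- names(epvs_regions())[-1]
  reg <- integer(nrow(instances))
  for (k in seq_len(nrow(instances))) {
    votes <- tabulate(atlas$grid[labels$grid == k] + 1L, nbins = 6L)
    reg[k] <- which.max(votes) - 1L       # ties -> smallest label code
  }
  counts <- vapply(1:5, function(l) sum(reg == l), 1L)
  names(counts) <- region_names
  voxvol <- atlas$geometry$voxel_volume_mm3
  region_volumes_cm3 <- vapply(1:5, function(l)
    sum(atlas$grid == l) * voxvol / 1000, numeric(1))
  names(region_volumes_cm3) <- region_names
  densities <- ifelse(region_volumes_cm3 > 0,
                      counts / region_volumes_cm3, NA_real_)
  tab <- cbind(instances, region = c("unassigned", region_names)[reg + 1L])
  structure(list(counts = counts, densities = densities,
                 region_volumes_cm3 = region_volumes_cm3,
                 cerebrum_total = nrow(instances),
                 unassigned = sum(reg == 0L),
                 table = tab),
            class = "epvs_summary")
}

#' @export
print.epvs_summary <- function(x, ...) {
  cat(sprintf("EPVS summary: %d instances in the cerebrum (%d unassigned)\n",
              x$cerebrum_total, x$unassigned))
  df <- data.frame(region = names(x$counts), count = x$counts,
                   density_per_cm3 = round(x$densities, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

# nearest-rank percentile
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

#' Fit the percentile-based ordinal binning scheme
#'
#' Counts up to the cohort median are used as is (lobar scheme); the
#' 50th-75th percentile range is split into three equal half-open
#' intervals (closed on the right) defining three ordinal levels, and
#' counts above the 75th percentile form one final level. The cerebrum
#' scheme additionally partitions `[0, p50]` into four equal-width levels,
#' giving exactly 8 ordinal levels. Percentiles use the nearest-rank
#' method. When p50 = p75 the interval levels collapse into one (with a
#' warning).
#'
#' @param counts non-negative integer EPVS counts over subjects (>= 4).
#' @param kind `"lobar"` or `"cerebrum"`.
#' @return a `binning_scheme` with `p50`, `p75` and interval `edges`.
#' @export
fit_binning <- function(counts, kind = c("lobar", "cerebrum")) {
  kind <- match.arg(kind)
  if (length(counts) < 4) stop("need at least 4 subjects")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  p50 <- nearest_rank(counts, 0.50)
  p75 <- nearest_rank(counts, 0.75)
  degenerate <- p75 <= p50
  if (degenerate)
    warning("p50 = p75: interval levels collapsed into a single level")
  edges <- if (degenerate) numeric(0)
           else p50 + (p75 - p50) * (1:3) / 3
  structure(list(kind = kind, p50 = p50, p75 = p75, edges = edges,
                 degenerate = degenerate),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("binning_scheme (%s): p50 = %g, p75 = %g\n",
              x$kind, x$p50, x$p75))
  if (!x$degenerate)
    cat("  interval edges:", paste(signif(x$edges, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Map a raw EPVS count to its ordinal level
#'
#' Lobar scheme: counts up to p50 map to themselves; counts in
#' `(p50, p75]` map to `p50 + 1 .. p50 + 3` by equal-width interval;
#' counts above p75 map to `p50 + 4`. Cerebrum scheme: `[0, p50]` maps to
#' levels 1-4 (equal width), `(p50, p75]` to 5-7, above p75 to 8.
#'
#' @param count non-negative count(s); vectorized.
#' @param scheme a [fit_binning()] scheme.
#' @return integer ordinal level(s).
#' @export
apply_binning <- function(count, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (any(count < 0)) stop("counts must be non-negative")
  p50 <- scheme$p50; p75 <- scheme$p75
  upper <- function(x) {
    # interval index 1..4 for counts above p50
    if (scheme$degenerate) return(rep(1L, length(x)))
    i <- pmin(4L, pmax(1L, ceiling(3 * (x - p50) / (p75 - p50))))
    i[x > p75] <- 4L
    i
  }
  if (scheme$kind == "lobar") {
    out <- ifelse(count <= p50, count, p50 + upper(count))
  } else {
    low <- if (p50 > 0) pmax(1L, ceiling(4 * count / p50)) else rep(1L, length(count))
    out <- ifelse(count <= p50, low, 4L + upper(count))
  }
  as.integer(out)
}

#' Per-subject quantification table
#'
#' The subjects-by-measures table consumed by downstream ordinal
#' regression / mixed-effects analyses: per-region counts, densities and
#' ordinal bins, plus the cerebrum total and its bin.
#'
#' @param summaries named list (by subject id) of `epvs_summary` objects.
#' @return data frame with one row per subject.
#' @export
epvs_subject_table <- function(summaries) {
  ids <- names(summaries)
  region_names <- names(epvs_regions())[-1]
  counts <- t(vapply(summaries, function(s) s$counts, numeric(5)))
  dens <- t(vapply(summaries, function(s) s$densities, numeric(5)))
  totals <- vapply(summaries, function(s) s$cerebrum_total, numeric(1))
  df <- data.frame(subject = ids)
  for (j in 1:5) {
    df[[paste0("count_", region_names[j])]] <- counts[, j]
    df[[paste0("density_", region_names[j])]] <- dens[, j]
  }
  df$count_cerebrum <- totals
  if (length(ids) >= 4) {
    for (j in 1:5) {
      sch <- fit_binning(counts[, j], "lobar")
      df[[paste0("bin_", region_names[j])]] <- apply_binning(counts[, j], sch)
    }
    sch <- fit_binning(totals, "cerebrum")
    df$bin_cerebrum <- apply_binning(totals, sch)
  }
  df
}
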