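#' Dice similarity coefficient between two binary masks
#'
#' `2|A and B| / (|A| + |B|)`, equal to `2TP / (2TP + FP + FN)` on any
#' confusion decomposition. Defined as 1 when both masks are empty (a
#' documented convention that only arises in degenerate cases).
#'
#' @param a,b `epvs_mask` objects (or logical arrays) of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' # worked example: 2992 true positives, 1400 missed, 1634 false positives
#' tp <- 2992; fn <- 1400; fp <- 1634
#' a <- array(rep(c(TRUE, FALSE), c(tp + fn, fp)), c(tp + fn + fp, 1, 1))
#' b <- array(rep(c(TRUE, FALSE, TRUE), c(tp, fn, fp)), dim(a))
#' round(dsc(a, b), 2)  # 0.66
dsc <- function(a, b) {
  ga <- if (inherits(a, "epvs_mask")) a$grid else a
  gb <- if (inherits(b, "epvs_mask")) b$grid else b
  if (!identical(dim(ga), dim(gb))) stop("mask shapes differ")
  na <- sum(ga); nb <- sum(gb)
  if (na + nb == 0) return(1)
  2 * sum(ga & gb) / (na + nb)
}

#' Generate evaluation ROIs containing hyperintense WM structures
#'
#' Randomly places fixed-size ROIs so that each contains at least one
#' connected cluster (>= 2 voxels) of white-matter voxels whose normalized
#' intensity exceeds the given percentile of the subject's WM intensities -
#' an automatable stand-in for "structures with intensities similar to the
#' manually segmented EPVS". `n_per_region` ROIs are produced for each of
#' the five regions; by default at most one ROI is taken per subject.
#'
#' @param subjects list of subjects (see [prepare_subject()]): each needs
#'   `inputs` (channel 1 = normalized image), `wm`, `atlas`.
#' @param n_per_region ROIs per region label (paper protocol: 20).
#' @param roi_size integer length-3 (default `c(25, 25, 9)` voxels).
#' @param intensity_percentile percentile of WM intensity defining
#'   "hyperintense" (default 90).
#' @param one_per_subject restrict to one ROI per subject (paper
#'   convention); set `FALSE` for small cohorts.
#' @return data frame of ROIs: subject, region, origin (`x0,y0,z0`,
#'   1-based) and size columns.
#' @export
generate_rois <- function(subjects, n_per_region = 20,
                          roi_size = c(25L, 25L, 9L),
                          intensity_percentile = 90,
                          one_per_subject = TRUE) {
  roi_size <- as.integer(roi_size)
  rois <- NULL
  used <- character()
  region_names <- names(epvs_regions())[-1]
  for (reg in 1:5) {
    placed <- 0
    order_subj <- sample(seq_along(subjects))
    n_pass <- if (one_per_subject) 1L else n_per_region
    for (rep_pass in seq_len(n_pass)) {
      for (si in order_subj) {
        if (placed >= n_per_region) break
        s <- subjects[[si]]
        if (one_per_subject && s$id %in% used) next
        cand <- roi_candidates(s, reg, intensity_percentile)
        if (is.null(cand)) next
        pick <- cand[sample.int(nrow(cand), 1L), ]
        dims <- s$inputs$dims
        org <- pmin(pmax(pick - roi_size %/% 2L, 1L), dims - roi_size + 1L)
        if (any(org < 1L)) next           # ROI larger than the volume
        rois <- rbind(rois, data.frame(subject = s$id, region = reg,
                                       region_name = region_names[reg],
                                       x0 = org[1], y0 = org[2], z0 = org[3],
                                       sx = roi_size[1], sy = roi_size[2],
                                       sz = roi_size[3]))
        used <- c(used, s$id)
        placed <- placed + 1
      }
      if (placed >= n_per_region) break
    }
    if (placed < n_per_region)
      stop(sprintf("region '%s' has too few subjects with qualifying hyperintense WM clusters (%d of %d ROIs placed)",
                   region_names[reg], placed, n_per_region))
  }
  rois$roi <- seq_len(nrow(rois))
  rois
}

# centre voxels (x,y,z) of hyperintense WM clusters (>= 2 voxels) within a
# region; NULL when none qualify
roi_candidates <- function(subject, region, intensity_percentile) {
  img <- subject$inputs$data[, 1]
  wm <- as.vector(subject$wm$grid)
  if (!any(wm)) return(NULL)
  thr <- quantile(img[wm], intensity_percentile / 100, names = FALSE)
  hot <- wm & img > thr & as.vector(subject$atlas$grid == region)
  if (!any(hot)) return(NULL)
  dims <- subject$inputs$dims
  lab <- cpp_cc_label(array(hot, dims), dims, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= 2)
  if (!length(keep)) return(NULL)
  ctrs <- t(vapply(keep, function(k) {
    round(colMeans(arrayInd(which(lab == k), dims)))
  }, numeric(3)))
  ctrs
}

# logical array marking the voxels of a set of ROI rows
roi_box <- function(roi_row, dims) {
  m <- array(FALSE, dims)
  m[roi_row$x0:(roi_row$x0 + roi_row$sx - 1),
    roi_row$y0:(roi_row$y0 + roi_row$sy - 1),
    roi_row$z0:(roi_row$z0 + roi_row$sz - 1)] <- TRUE
  m
}

#' Match ground-truth instances against a predicted segmentation
#'
#' One record per ground-truth EPVS instance intersecting any of the
#' subject's ROIs; an instance counts as detected when at least one of its
#' voxels is also segmented in the prediction.
#'
#' @param gt_labels instance-labelled ground truth ([epvs_labels()] or an
#'   integer array); a plain binary mask is rejected - label instances
#'   first with [extract_instances()].
#' @param pred_mask predicted [epvs_mask()].
#' @param rois data frame of this subject's ROIs (see [generate_rois()]).
#' @return data frame: instance id, `volume_mm3`, `detected`, `roi`.
#' @export
match_detections <- function(gt_labels, pred_mask, rois) {
  if (inherits(gt_labels, "epvs_mask") || is.logical(gt_labels))
    stop("ground truth is a plain binary mask; label instances first (extract_instances)")
  lab <- if (inherits(gt_labels, "epvs_labels")) gt_labels$grid else gt_labels
  geom <- if (inherits(gt_labels, "epvs_labels")) gt_labels$geometry
          else pred_mask$geometry
  if (!identical(dim(lab), dim(pred_mask$grid)))
    stop("ground truth and prediction are not aligned")
  recs <- NULL
  seen <- integer()
  for (i in seq_len(nrow(rois))) {
    box <- roi_box(rois[i, ], dim(lab))
    ids <- setdiff(unique(lab[box]), c(0L, seen))
    for (id in ids) {
      vox <- lab == id
      recs <- rbind(recs, data.frame(
        instance = id,
        volume_mm3 = sum(vox) * geom$voxel_volume_mm3,
        detected = any(pred_mask$grid[vox]),
        roi = rois$roi[i]))
      seen <- c(seen, id)
    }
  }
  if (is.null(recs))
    recs <- data.frame(instance = integer(), volume_mm3 = numeric(),
                       detected = logical(), roi = integer())
  recs
}

#' Size-binned detection sensitivity
#'
#' For each size threshold t, the proportion of ground-truth instances
#' with volume strictly larger than t that were detected. An empty bin is
#' reported as `NA` (undefined), not 0.
#'
#' @param records detection records (possibly pooled over subjects); see
#'   [match_detections()].
#' @param size_thresholds_mm3 thresholds in mm^3 (default 0, 3, 12).
#' @return named numeric vector of proportions.
#' @export
#' @examples
#' r <- data.frame(volume_mm3 = rep(1, 351),
#'                 detected = rep(c(TRUE, FALSE), c(237, 114)))
#' round(100 * sensitivity(r, 0))  # 68 (percent)
sensitivity <- function(records, size_thresholds_mm3 = c(0, 3, 12)) {
  out <- vapply(size_thresholds_mm3, function(t) {
    sel <- records$volume_mm3 > t
    if (!any(sel)) return(NA_real_)
    mean(records$detected[sel])
  }, numeric(1))
  names(out) <- paste0(">", size_thresholds_mm3, "mm3")
  out
}

#' Per-ROI voxel-count correlation
#'
#' Pearson correlation between the manually and automatically segmented
#' voxel counts per ROI (segmentation consistency). Undefined (NA, with a
#' warning) when either list has zero variance.
#'
#' @param manual,auto equal-length numeric vectors (length >= 3).
#' @return Pearson r.
#' @export
count_correlation <- function(manual, auto) {
  if (length(manual) != length(auto)) stop("paired lists differ in length")
  if (length(manual) < 3) stop("need at least 3 paired ROIs")
  if (sd(manual) == 0 || sd(auto) == 0) {
    warning("zero variance in voxel counts; correlation undefined")
    return(NA_real_)
  }
  cor(manual, auto)
}

#' Evaluate an ensemble on a labelled cohort
#'
#' Runs the full evaluation protocol: ROI generation, per-instance
#' detection matching, size-binned sensitivity, Dice overlap pooled over
#' ROI voxels, and the per-ROI manual/automatic voxel-count correlation.
#'
#' @param predictions named list (by subject id) of predicted `epvs_mask`s.
#' @param subjects the labelled subjects.
#' @param rois data frame from [generate_rois()].
#' @param size_thresholds_mm3 sensitivity size bins.
#' @return an `epvs_eval_report`: list with `sensitivity`, `dsc`,
#'   `count_correlation`, `records`, `per_roi`.
#' @export
evaluate_ensemble <- function(predictions, subjects, rois,
                              size_thresholds_mm3 = c(0, 3, 12)) {
  records <- NULL
  per_roi <- NULL
  tp <- fp <- fn <- 0
  for (s in subjects) {
    rs <- rois[rois$subject == s$id, , drop = FALSE]
    if (!nrow(rs)) next
    pred <- predictions[[s$id]]
    rec <- match_detections(s$gt_labels, pred, rs)
    records <- rbind(records, cbind(subject = s$id, rec))
    for (i in seq_len(nrow(rs))) {
      box <- roi_box(rs[i, ], dim(pred$grid))
      g <- s$gt_labels$grid[box] > 0
      p <- pred$grid[box]
      tp <- tp + sum(g & p); fp <- fp + sum(!g & p); fn <- fn + sum(g & !p)
      per_roi <- rbind(per_roi, data.frame(
        roi = rs$roi[i], subject = s$id, region = rs$region_name[i],
        manual_voxels = sum(g), auto_voxels = sum(p)))
    }
  }
  r <- tryCatch(count_correlation(per_roi$manual_voxels, per_roi$auto_voxels),
                warning = function(w) NA_real_)
  structure(list(
    sensitivity = sensitivity(records, size_thresholds_mm3),
    dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    count_correlation = r,
    records = records, per_roi = per_roi), class = "epvs_eval_report")
}

#' @export
print.epvs_eval_report <- function(x, ...) {
  cat("EPVS ensemble evaluation\n")
  cat("  sensitivity:",
      paste(sprintf("%s = %.0f%%", names(x$sensitivity),
                    100 * x$sensitivity), collapse = ", "), "\n")
  cat(sprintf("  DSC over ROI voxels: %.3f\n", x$dsc))
  cat(sprintf("  per-ROI count correlation: %.3f\n", x$count_correlation))
  invisible(x)
}
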