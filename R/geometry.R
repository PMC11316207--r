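#' Voxel geometry of an anisotropic image grid
#'
#' Physical voxel spacing in millimetres along x, y, z. The default matches
#' a 2D multi-echo spin-echo ex vivo acquisition with 0.6 mm in-plane
#' resolution and 1.5 mm slice thickness, giving a voxel volume of
#' 0.54 mm^3.
#'
#' @param spacing_mm numeric length-3, positive spacings (dx, dy, dz) in mm.
#' @return An object of class `voxel_geometry` with elements `spacing_mm`
#'   and `voxel_volume_mm3`.
#' @export
#' @examples
#' g <- voxel_geometry()
#' g$voxel_volume_mm3  # 0.54
voxel_geometry <- function(spacing_mm = c(0.6, 0.6, 1.5)) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be three positive finite values")
  structure(list(spacing_mm = spacing_mm,
                 voxel_volume_mm3 = prod(spacing_mm)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.4g x %.4g x %.4g mm (%.4g mm^3/voxel)\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$voxel_volume_mm3))
  invisible(x)
}

#' Scalar intensity volume on a voxel grid
#'
#' @param grid 3D numeric array, all values finite.
#' @param geometry a [voxel_geometry()].
#' @return An `epvs_volume` object (list with `grid`, `geometry`).
#' @export
epvs_volume <- function(grid, geometry = voxel_geometry()) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3 || any(dim(grid) < 1))
    stop("grid must be a 3D array")
  if (!all(is.finite(grid))) stop("grid contains non-finite values")
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(grid = grid, geometry = geometry), class = "epvs_volume")
}

#' Binary mask on a voxel grid
#'
#' @param grid 3D logical (or 0/1) array.
#' @inheritParams epvs_volume
#' @return An `epvs_mask` object.
#' @export
epvs_mask <- function(grid, geometry = voxel_geometry()) {
  grid <- array(as.logical(grid), dim = dim(as.array(grid)))
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (any(is.na(grid))) stop("mask contains NA")
  structure(list(grid = grid, geometry = geometry), class = "epvs_mask")
}

#' Region codes of the lobar + basal ganglia atlas
#'
#' Integer labels 0 (background), 1 frontal, 2 parietal, 3 temporal,
#' 4 occipital, 5 basal ganglia.
#' @export
epvs_regions <- function() {
  c(background = 0L, frontal = 1L, parietal = 2L, temporal = 3L,
    occipital = 4L, basal_ganglia = 5L)
}

#' Regional atlas volume (6 labels)
#'
#' @param grid 3D integer array with codes in 0..5 (see [epvs_regions()]).
#' @inheritParams epvs_volume
#' @return An `epvs_atlas` object.
#' @export
epvs_atlas <- function(grid, geometry = voxel_geometry()) {
  grid <- array(as.integer(grid), dim = dim(as.array(grid)))
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (any(is.na(grid)) || any(grid < 0L) || any(grid > 5L))
    stop("atlas labels must be integers in 0..5")
  structure(list(grid = grid, geometry = geometry), class = "epvs_atlas")
}

#' @export
print.epvs_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("epvs_volume %d x %d x %d, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$grid), max(x$grid)))
  print(x$geometry)
  invisible(x)
}

#' @export
print.epvs_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("epvs_mask %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$grid)))
  invisible(x)
}

#' @export
print.epvs_atlas <- function(x, ...) {
  d <- dim(x$grid)
  tab <- table(factor(x$grid, levels = 0:5,
                      labels = names(epvs_regions())))
  cat(sprintf("epvs_atlas %d x %d x %d\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

# grids compared by shape + spacing with 1e-4 mm tolerance
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$grid), dim(b$grid)) &&
    all(abs(a$geometry$spacing_mm - b$geometry$spacing_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (shape/spacing mismatch)")
  invisible(TRUE)
}

#' Visualize an axial slice of a volume
#'
#' @param x an `epvs_volume`.
#' @param slice z index (default middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.epvs_volume <- function(x, slice = NULL, ...) {
  d <- dim(x$grid)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  graphics::image(seq_len(d[1]) * x$geometry$spacing_mm[1],
                  seq_len(d[2]) * x$geometry$spacing_mm[2],
                  x$grid[, , slice], asp = 1, col = grey.colors(128),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("slice z = %d", slice), ...)
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into an `epvs_volume` / `epvs_mask` / `epvs_atlas`;
#' the voxel spacing is taken from the header and the full image object is
#' kept so the affine survives a round-trip.
#'
#' @param path file path to a `.nii` / `.nii.gz` file.
#' @param as one of "volume", "mask", "atlas".
#' @return the corresponding object, with the RNifti image in
#'   `attr(, "nifti")`.
#' @export
read_volume <- function(path, as = c("volume", "mask", "atlas")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  geom <- voxel_geometry(sp)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  out <- switch(as,
                volume = epvs_volume(arr, geom),
                mask = epvs_mask(arr != 0, geom),
                atlas = epvs_atlas(round(arr), geom))
  attr(out, "nifti") <- img
  out
}

#' Write a volume/mask/atlas to NIfTI
#'
#' If the object was read from disk its original header (affine included)
#' is reused verbatim; otherwise a header is constructed from the spacing.
#'
#' @param x an `epvs_volume`, `epvs_mask`, `epvs_atlas`, or a plain 3D
#'   array accompanied by `geometry`.
#' @param path output file path.
#' @param geometry used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, geometry = NULL) {
  if (is.array(x)) x <- epvs_volume(x, geometry %||% voxel_geometry())
  grid <- x$grid
  storage.mode(grid) <- if (inherits(x, "epvs_volume")) "double" else "integer"
  tpl <- attr(x, "nifti")
  if (!is.null(tpl)) {
    img <- RNifti::updateNifti(grid, template = tpl)
  } else {
    img <- RNifti::asNifti(grid)
    RNifti::pixdim(img) <- x$geometry$spacing_mm
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
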