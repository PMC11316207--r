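## Multi-scale curvilinear-structure feature bank.
##
## All kernels are defined in physical units (mm) and converted to voxel
## units per axis, so responses are consistent on anisotropic grids.
## Derivative kernels are moment-corrected: the discrete first-derivative
## kernel reproduces the slope of a linear ramp exactly, the second-
## derivative kernel the curvature of a parabola.

gauss_kernel_1d <- function(sigma_mm, dx_mm, order = 0L) {
  if (sigma_mm <= 0) stop("sigma must be positive")
  s <- sigma_mm / dx_mm                      # sigma in voxel units
  r <- max(1L, ceiling(3.5 * s))
  j <- (-r):r
  g <- exp(-j^2 / (2 * s^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- j * g                               # proportional to -G'
    k <- k - mean(k)
    k / sum(k * j * dx_mm)                   # ramp a*x -> a
  } else if (order == 2L) {
    k <- (j^2 / s^2 - 1) * g                 # proportional to G''
    k <- k - mean(k)
    k / sum(k * (j * dx_mm)^2 / 2)           # parabola a*x^2/2 -> a
  } else stop("order must be 0, 1 or 2")
}

# Separable filter: per-axis Gaussian of given derivative orders.
filter_separable <- function(grid, spacing, sigma_mm, orders) {
  d <- dim(grid)
  x <- as.numeric(grid)
  for (ax in 1:3)
    x <- cpp_filter_axis(x, d, gauss_kernel_1d(sigma_mm, spacing[ax],
                                               orders[ax]), ax - 1L)
  array(x, dim = d)
}

#' Gaussian smoothing of a volume
#'
#' Separable, anisotropy-aware Gaussian of physical width `sigma_mm` with
#' reflective boundaries.
#'
#' @param vol an [epvs_volume()].
#' @param sigma_mm Gaussian standard deviation in mm.
#' @return smoothed `epvs_volume`.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  epvs_volume(filter_separable(vol$grid, vol$geometry$spacing_mm, sigma_mm,
                               c(0L, 0L, 0L)), vol$geometry)
}

# Gaussian-derivative gradient (3 arrays) and Hessian (6 arrays: xx, yy,
# zz, xy, xz, yz) at scale sigma_mm, in physical units per mm.
gauss_gradient <- function(grid, spacing, sigma_mm) {
  list(gx = filter_separable(grid, spacing, sigma_mm, c(1L, 0L, 0L)),
       gy = filter_separable(grid, spacing, sigma_mm, c(0L, 1L, 0L)),
       gz = filter_separable(grid, spacing, sigma_mm, c(0L, 0L, 1L)))
}

gauss_hessian <- function(grid, spacing, sigma_mm) {
  list(hxx = filter_separable(grid, spacing, sigma_mm, c(2L, 0L, 0L)),
       hyy = filter_separable(grid, spacing, sigma_mm, c(0L, 2L, 0L)),
       hzz = filter_separable(grid, spacing, sigma_mm, c(0L, 0L, 2L)),
       hxy = filter_separable(grid, spacing, sigma_mm, c(1L, 1L, 0L)),
       hxz = filter_separable(grid, spacing, sigma_mm, c(1L, 0L, 1L)),
       hyz = filter_separable(grid, spacing, sigma_mm, c(0L, 1L, 1L)))
}

# ---------------------------------------------------------------------------
# feature stacks: nvox x F matrix + names + grid metadata

new_stack <- function(data, names, dims, geometry) {
  if (!all(is.finite(data))) stop("feature stack contains non-finite values")
  structure(list(data = data, names = names, dims = as.integer(dims),
                 geometry = geometry), class = "epvs_stack")
}

#' Number of maps in a feature stack
#' @param stack an `epvs_stack`.
#' @export
n_features <- function(stack) ncol(stack$data)

#' Extract one feature map as a 3D array
#' @param stack an `epvs_stack`.
#' @param i map index or name.
#' @export
stack_map <- function(stack, i) {
  if (is.character(i)) i <- match(i, stack$names)
  array(stack$data[, i], dim = stack$dims)
}

#' @export
print.epvs_stack <- function(x, ...) {
  cat(sprintf("epvs_stack: %d maps on %d x %d x %d grid\n",
              n_features(x), x$dims[1], x$dims[2], x$dims[3]))
  if (n_features(x) <= 24) cat(paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

c_stacks <- function(...) {
  xs <- list(...)
  new_stack(do.call(cbind, lapply(xs, `[[`, "data")),
            unlist(lapply(xs, `[[`, "names")),
            xs[[1]]$dims, xs[[1]]$geometry)
}

#' Default steerable-filter orientation set
#'
#' Nine unit vectors: the three grid axes plus the six face-diagonal
#' directions of one hemisphere, a fixed deterministic list.
#' @return 9 x 3 matrix of unit vectors.
#' @export
steerable_orientations <- function() {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  v / sqrt(rowSums(v^2))
}

#' Steerable Gaussian-derivative features (19 maps per scale)
#'
#' The Gaussian response at scale `sigma_mm` plus, for each of nine
#' orientations v, the directional first derivative g.v and directional
#' second derivative v'Hv, computed analytically from the Gaussian
#' gradient and Hessian (steered responses). Derivatives are in physical
#' units (per mm), spacing-aware.
#'
#' @param vol an [epvs_volume()] (normalized image or its top-hat).
#' @param sigma_mm filter scale in mm.
#' @param orientations 9 x 3 matrix of unit vectors.
#' @return an `epvs_stack` of exactly 19 maps.
#' @export
steerable_features <- function(vol, sigma_mm,
                               orientations = steerable_orientations()) {
  orientations <- as.matrix(orientations)
  if (nrow(orientations) != 9 || ncol(orientations) != 3)
    stop("orientations must be a 9 x 3 matrix")
  if (any(abs(sqrt(rowSums(orientations^2)) - 1) > 1e-8))
    stop("orientations must be unit vectors")
  sp <- vol$geometry$spacing_mm
  if (sigma_mm < min(sp) / 2) stop("sigma too small for the voxel grid")
  G <- filter_separable(vol$grid, sp, sigma_mm, c(0L, 0L, 0L))
  gr <- gauss_gradient(vol$grid, sp, sigma_mm)
  H <- gauss_hessian(vol$grid, sp, sigma_mm)
  nvox <- length(G)
  data <- matrix(0, nvox, 19)
  data[, 1] <- G
  for (k in 1:9) {
    v <- orientations[k, ]
    data[, 1 + k] <- v[1] * gr$gx + v[2] * gr$gy + v[3] * gr$gz
    data[, 10 + k] <- v[1]^2 * H$hxx + v[2]^2 * H$hyy + v[3]^2 * H$hzz +
      2 * (v[1] * v[2] * H$hxy + v[1] * v[3] * H$hxz + v[2] * v[3] * H$hyz)
  }
  nms <- c("gauss", paste0("d1.o", 1:9), paste0("d2.o", 1:9))
  new_stack(data, nms, dim(vol$grid), vol$geometry)
}

# magnitude-sort three algebraically sorted eigenvalue columns
mag_sort_eigs <- function(E) {
  a <- abs(E)
  n <- nrow(E)
  i1 <- max.col(-a, ties.method = "first")
  i3 <- max.col(a, ties.method = "last")
  tie <- i1 == i3                            # all-equal magnitudes
  i3[tie] <- (i1[tie] %% 3L) + 1L
  i2 <- 6L - i1 - i3
  cbind(E[cbind(seq_len(n), i1)], E[cbind(seq_len(n), i2)],
        E[cbind(seq_len(n), i3)])
}

#' Frangi vesselness features (5 maps per scale)
#'
#' From the scale-normalized Hessian (entries multiplied by sigma^2,
#' gamma = 2 convention): the three eigenvalues sorted by magnitude
#' |l1| <= |l2| <= |l3|, the bright-tube vesselness (EPVS are hyperintense,
#' so the response is zero wherever l2 > 0 or l3 > 0), and the
#' second-order structureness S (Frobenius norm of the Hessian).
#'
#' @param vol an [epvs_volume()].
#' @param sigma_mm filter scale in mm.
#' @param alpha,beta_ plate/blob discrimination parameters (defaults 0.5).
#' @return an `epvs_stack` of exactly 5 maps
#'   (`lambda1`, `lambda2`, `lambda3`, `vesselness`, `structureness`).
#' @export
frangi_features <- function(vol, sigma_mm, alpha = 0.5, beta_ = 0.5) {
  sp <- vol$geometry$spacing_mm
  if (sigma_mm < min(sp) / 2) stop("sigma too small for the voxel grid")
  H <- gauss_hessian(vol$grid, sp, sigma_mm)
  s2 <- sigma_mm^2
  E <- cpp_sym3_eigs(s2 * as.numeric(H$hxx), s2 * as.numeric(H$hyy),
                     s2 * as.numeric(H$hzz), s2 * as.numeric(H$hxy),
                     s2 * as.numeric(H$hxz), s2 * as.numeric(H$hyz))
  L <- mag_sort_eigs(E)
  S <- sqrt(rowSums(E^2))
  cnorm <- max(S) / 2
  V <- numeric(nrow(L))
  ok <- L[, 2] <= 0 & L[, 3] < 0
  if (any(ok) && cnorm > 0) {
    Ra <- abs(L[ok, 2]) / abs(L[ok, 3])
    Rb <- abs(L[ok, 1]) / sqrt(abs(L[ok, 2] * L[ok, 3]))
    V[ok] <- (1 - exp(-Ra^2 / (2 * alpha^2))) *
      exp(-Rb^2 / (2 * beta_^2)) *
      (1 - exp(-S[ok]^2 / (2 * cnorm^2)))
  }
  new_stack(cbind(L, V, S),
            c("lambda1", "lambda2", "lambda3", "vesselness",
              "structureness"),
            dim(vol$grid), vol$geometry)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Optimally oriented flux features (5 maps per radius)
#'
#' The oriented-flux matrix at each voxel is the (symmetrized) outward flux
#' of the Gaussian-regularized image gradient through the sphere of radius
#' `radius_mm`, estimated by quasi-uniform spherical-shell sampling with
#' trilinear interpolation and normalized by the number of surface samples.
#' Maps: three eigenvalues sorted ascending, the bright-tube measure
#' (geometric mean of the two most negative eigenvalues, clamped at zero),
#' and the Frobenius norm.
#'
#' @param vol an [epvs_volume()].
#' @param radius_mm sphere radius in mm; sub-voxel radii (down to half
#'   the smallest spacing) are supported through the trilinear shell
#'   sampling.
#' @param pre_sigma_mm width of the Gaussian used to regularize the
#'   gradient field (default: the smallest voxel spacing).
#' @param n_points number of sphere surface samples (default 120).
#' @return an `epvs_stack` of exactly 5 maps.
#' @export
oof_features <- function(vol, radius_mm, pre_sigma_mm = NULL,
                         n_points = 120) {
  sp <- vol$geometry$spacing_mm
  if (radius_mm < min(sp) / 2)
    stop("radius must be at least half the smallest spacing")
  ext <- dim(vol$grid) * sp
  if (radius_mm > min(ext) / 2)
    stop("radius exceeds half the smallest volume extent")
  if (is.null(pre_sigma_mm)) pre_sigma_mm <- min(sp)
  gr <- gauss_gradient(vol$grid, sp, pre_sigma_mm)
  pts <- fibonacci_sphere(n_points)
  off <- sweep(pts * radius_mm, 2, sp, "/")
  Q <- cpp_sphere_flux(as.numeric(gr$gx), as.numeric(gr$gy),
                       as.numeric(gr$gz), dim(vol$grid), pts, off)
  E <- cpp_sym3_eigs(Q[, 1], Q[, 2], Q[, 3], Q[, 4], Q[, 5], Q[, 6])
  tube <- ifelse(E[, 2] < 0, sqrt(pmax(E[, 1] * E[, 2], 0)), 0)
  frob <- sqrt(rowSums(E^2))
  new_stack(cbind(E, tube, frob),
            c("eig1", "eig2", "eig3", "tube", "frobenius"),
            dim(vol$grid), vol$geometry)
}

#' Filter-bank configuration
#'
#' Scales and switches for the multi-scale feature bank. The default
#' configuration uses 3 steerable scales, 12 Frangi scales and 12 OOF
#' radii (log-spaced over 0.4-3.0 mm, bracketing EPVS radii representable
#' at 0.6 mm in-plane resolution) on both the image and its white top-hat
#' transform: (19 x 3 + 5 x 12 + 5 x 12) x 2 = 354 features.
#'
#' @param sf_sigmas_mm steerable-filter scales (mm).
#' @param ff_sigmas_mm Frangi scales (mm).
#' @param oof_radii_mm OOF radii (mm).
#' @param sf_orientations 9 x 3 unit-vector matrix.
#' @param use_tophat_branch also run the bank on the top-hat transform.
#' @param tophat_radius_mm structuring-element radius for the top-hat.
#' @return a `filter_bank_config` object.
#' @export
#' @examples
#' feature_count(filter_bank_config())  # 354
filter_bank_config <- function(sf_sigmas_mm = c(0.5, 1, 2),
                               ff_sigmas_mm = exp(seq(log(0.4), log(3),
                                                      length.out = 12)),
                               oof_radii_mm = exp(seq(log(0.4), log(3),
                                                      length.out = 12)),
                               sf_orientations = steerable_orientations(),
                               use_tophat_branch = TRUE,
                               tophat_radius_mm = 1.2) {
  chk <- function(x, nm) {
    if (length(x) && (any(x <= 0) || is.unsorted(x, strictly = TRUE)))
      stop(nm, " must be strictly increasing and positive")
  }
  chk(sf_sigmas_mm, "sf_sigmas_mm"); chk(ff_sigmas_mm, "ff_sigmas_mm")
  chk(oof_radii_mm, "oof_radii_mm")
  structure(list(sf_sigmas_mm = sf_sigmas_mm, ff_sigmas_mm = ff_sigmas_mm,
                 oof_radii_mm = oof_radii_mm,
                 sf_orientations = sf_orientations,
                 use_tophat_branch = isTRUE(use_tophat_branch),
                 tophat_radius_mm = tophat_radius_mm),
            class = "filter_bank_config")
}

#' Number of features a configuration produces
#' @param config a [filter_bank_config()].
#' @export
feature_count <- function(config) {
  (1 + config$use_tophat_branch) *
    (19 * length(config$sf_sigmas_mm) + 5 * length(config$ff_sigmas_mm) +
       5 * length(config$oof_radii_mm))
}

#' Assemble the full multi-scale feature stack
#'
#' Runs the steerable / Frangi / OOF filters at every configured scale on
#' the (normalized) image and, if enabled, on its white top-hat transform,
#' concatenated in the deterministic order branch > filter family > scale >
#' component. The default configuration yields 354 maps (177 per branch).
#'
#' @param vol a robust-Z normalized [epvs_volume()].
#' @param config a [filter_bank_config()].
#' @return an `epvs_stack`.
#' @export
assemble_feature_stack <- function(vol, config = filter_bank_config()) {
  stopifnot(inherits(vol, "epvs_volume"),
            inherits(config, "filter_bank_config"))
  branch <- function(v, tag) {
    parts <- list()
    for (s in config$sf_sigmas_mm) {
      st <- steerable_features(v, s, config$sf_orientations)
      st$names <- sprintf("%s.sf.s%.3g.%s", tag, s, st$names)
      parts[[length(parts) + 1]] <- st
    }
    for (s in config$ff_sigmas_mm) {
      st <- frangi_features(v, s)
      st$names <- sprintf("%s.ff.s%.3g.%s", tag, s, st$names)
      parts[[length(parts) + 1]] <- st
    }
    for (r in config$oof_radii_mm) {
      st <- oof_features(v, r)
      st$names <- sprintf("%s.oof.r%.3g.%s", tag, r, st$names)
      parts[[length(parts) + 1]] <- st
    }
    do.call(c_stacks, parts)
  }
  out <- branch(vol, "raw")
  if (config$use_tophat_branch) {
    th <- white_tophat(vol, config$tophat_radius_mm)
    out <- c_stacks(out, branch(th, "tophat"))
  }
  out
}
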