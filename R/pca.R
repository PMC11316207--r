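#' Fit a PCA model on masked feature-stack voxels
#'
#' Per-feature centring followed by an eigen-decomposition of the sample
#' covariance of the (masked voxels x features) matrix. Components follow a
#' deterministic sign convention - the largest-magnitude entry of each
#' loading is positive - so downstream training is reproducible. The model
#' records the explained-variance ratio of the kept components.
#'
#' @param stack an `epvs_stack` (see [assemble_feature_stack()]).
#' @param mask an [epvs_mask()]; statistics use only masked voxels.
#' @param n_components number of components to keep (default 12).
#' @return an `epvs_pca` object with `mean`, `loadings` (orthonormal
#'   columns), `explained_variance_ratio`, `n_components`.
#' @export
fit_pca <- function(stack, mask, n_components = 12) {
  stopifnot(inherits(stack, "epvs_stack"), inherits(mask, "epvs_mask"))
  if (!identical(stack$dims, dim(mask$grid)))
    stop("stack and mask are not on the same grid")
  X <- stack$data[as.logical(mask$grid), , drop = FALSE]
  p <- ncol(X)
  if (nrow(X) <= p)
    stop("need more masked voxels than features to fit the PCA")
  if (n_components > p) stop("n_components exceeds the feature count")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  if (vals[n_components] <= max(vals) * 1e-10)
    stop("rank-deficient input: n_components exceeds the numerical rank")
  W <- ee$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(mean = mu,
                 loadings = W,
                 eigenvalues = vals[seq_len(n_components)],
                 explained_variance_ratio =
                   vals[seq_len(n_components)] / sum(vals),
                 total_variance = sum(vals),
                 n_components = n_components),
            class = "epvs_pca")
}

#' @export
print.epvs_pca <- function(x, ...) {
  cat(sprintf("epvs_pca: %d components over %d features; cumulative variance %.1f%%\n",
              x$n_components, length(x$mean),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project a feature stack onto PCA components
#'
#' Voxel-wise projection producing `n_components` maps (the
#' "EPVS-enhanced" features fed to the network).
#'
#' @param stack an `epvs_stack` whose feature count matches the model.
#' @param model an `epvs_pca` from [fit_pca()].
#' @return an `epvs_stack` with `n_components` maps.
#' @export
transform_pca <- function(stack, model) {
  stopifnot(inherits(stack, "epvs_stack"), inherits(model, "epvs_pca"))
  if (ncol(stack$data) != length(model$mean))
    stop("stack feature count does not match the PCA input dimension")
  scores <- sweep(stack$data, 2, model$mean) %*% model$loadings
  new_stack(scores, paste0("pca", seq_len(model$n_components)),
            stack$dims, stack$geometry)
}
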