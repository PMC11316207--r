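#' Network configuration for the two-stage triple U-Net
#'
#' Three structurally identical U-Nets in a two-stage layout: two parallel
#' U-Nets (A, B) read the 19-channel input; the second-stage U-Net (C)
#' merges their feature maps, with concatenation skips between U-Nets at
#' every encoder and decoder level. Convolutional blocks are 3x3x3 kernels,
#' stride 1, zero padding, ReLU then batch normalization; inputs are
#' downsampled three times by 2x2x2 max pooling, with one extra 4x4x4
#' stride-4 pool feeding the raw network input directly into the
#' quarter-resolution encoder level; the first two decreasing levels use a
#' dual path (convolution-then-pool alongside pool-then-convolution, fused
#' by concatenation); the decoder upsamples by nearest neighbour. Each
#' U-Net ends in a 1x1x1 sigmoid head. The stage-1 heads are trained with
#' recall-oriented (beta = 10) and precision-oriented (beta = 0.1) F-beta
#' losses, the stage-2 head with beta = 1, and only the stage-2 head is
#' used at inference.
#'
#' @param in_channels input channels (1 image + 12 PCA + 1 WM mask +
#'   5 lobar masks = 19 in the default pipeline).
#' @param base_channels channels per convolutional block (64; reducible
#'   for CPU-scale runs).
#' @param convs_per_level convolution blocks per resolution level.
#' @param betas length-3 F-beta parameters for heads (A, B, C).
#' @param epsilon loss stabilizer.
#' @param dropconnect_p per-weight DropConnect probability during training.
#' @param l2_weight L2 penalty applied to convolution kernels by the
#'   optimizer.
#' @param head_bias_init initial bias of the sigmoid output heads;
#'   the default -3 (foreground prior of about 5 percent) matches the
#'   sparsity of EPVS voxels and avoids spending early optimization
#'   steps unlearning a 50 percent prior.
#' @return a `network_config` object.
#' @export
network_config <- function(in_channels = 19L, base_channels = 64L,
                           convs_per_level = 2L, betas = c(10, 0.1, 1),
                           epsilon = 1e-3, dropconnect_p = 0.3,
                           l2_weight = 0.001, head_bias_init = -3) {
  if (length(betas) != 3 || any(betas <= 0)) stop("betas must be 3 positive values")
  if (dropconnect_p < 0 || dropconnect_p >= 1) stop("dropconnect_p must be in [0, 1)")
  if (base_channels < 1 || in_channels < 1) stop("channel counts must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_downsamplings = 3L,
                 convs_per_level = as.integer(convs_per_level),
                 betas = as.numeric(betas), epsilon = epsilon,
                 dropconnect_p = dropconnect_p, l2_weight = l2_weight,
                 head_bias_init = head_bias_init),
            class = "network_config")
}

# One resolution-level block: convs_per_level x (conv3 -> ReLU -> BN)
unet_block <- function(T, x, name) {
  for (k in seq_len(T$model$cfg$convs_per_level))
    x <- op_bn(T, op_relu(T, op_conv3(T, x, sprintf("%s.c%d", name, k))),
               sprintf("%s.n%d", name, k))
  x
}

# One U-Net. `cross` is NULL for stage 1, or the feature list of the two
# stage-1 U-Nets for the stage-2 net (concatenated at every level).
unet_forward <- function(T, x, prefix, cross = NULL) {
  nm <- function(s) paste(prefix, s, sep = ".")
  cc <- function(u, lev) {
    if (is.null(cross)) u
    else op_concat(T, u, cross[[1]][[lev]], cross[[2]][[lev]])
  }
  u0 <- cc(x, "b1")
  b1 <- unet_block(T, u0, nm("b1"))
  u1 <- op_concat(T, op_pool(T, b1, 2L),
                  unet_block(T, op_pool(T, u0, 2L), nm("t1")))
  u1 <- cc(u1, "b2")
  b2 <- unet_block(T, u1, nm("b2"))
  u2 <- op_concat(T, op_pool(T, b2, 2L),
                  unet_block(T, op_pool(T, u1, 2L), nm("t2")),
                  op_pool(T, x, 4L))
  u2 <- cc(u2, "b3")
  b3 <- unet_block(T, u2, nm("b3"))
  b4 <- unet_block(T, cc(op_pool(T, b3, 2L), "b4"), nm("b4"))
  d3 <- unet_block(T, cc(op_concat(T, op_up2(T, b4), b3), "d3"), nm("d3"))
  d2 <- unet_block(T, cc(op_concat(T, op_up2(T, d3), b2), "d2"), nm("d2"))
  d1 <- unet_block(T, cc(op_concat(T, op_up2(T, d2), b1), "d1"), nm("d1"))
  head <- op_sigmoid(T, op_conv1(T, d1, nm("head")))
  list(head = head,
       feats = list(b1 = b1, b2 = b2, b3 = b3, b4 = b4,
                    d3 = d3, d2 = d2, d1 = d1))
}

# Full two-stage forward pass. x: (nvox x in_channels) matrix with a
# "dims" attribute. Returns the tape and the three sigmoid heads.
forward_triple <- function(model, x, training = FALSE) {
  if (ncol(x) != model$cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d",
                 model$cfg$in_channels, ncol(x)))
  dims <- attr(x, "dims")
  if (is.null(dims) || prod(dims) != nrow(x))
    stop("input patch must carry a 'dims' attribute matching its rows")
  T <- tape_new(model, training)
  x <- tp_val(T, x, attr(x, "dims"), needs_grad = FALSE)
  A <- unet_forward(T, x, "A")
  B <- unet_forward(T, x, "B")
  xc <- op_concat(T, A$feats$d1, B$feats$d1)
  C <- unet_forward(T, xc, "C", cross = list(A$feats, B$feats))
  list(tape = T, pA = A$head, pB = B$head, pC = C$head)
}

#' Build the two-stage triple-U-Net model
#'
#' Instantiates all parameters (He-initialized convolution kernels, batch
#' normalization scale/shift and running statistics) deterministically
#' under `seed` by tracing one forward pass on a dummy patch.
#'
#' @param config a [network_config()].
#' @param seed integer seed controlling weight initialization.
#' @return an `epvs_segmodel` (environment) with `pars`, `buffers`,
#'   `cfg`, and `n_parameters`.
#' @export
build_model <- function(config = network_config(), seed = 1L) {
  model <- new.env(parent = emptyenv())
  model$cfg <- config
  model$pars <- new.env(parent = emptyenv())
  model$buffers <- new.env(parent = emptyenv())
  model$kind <- new.env(parent = emptyenv())
  class(model) <- "epvs_segmodel"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dummy <- matrix(0, 8 * 8 * 8, config$in_channels)
  attr(dummy, "dims") <- c(8L, 8L, 8L)
  invisible(forward_triple(model, dummy, training = FALSE))
  model$n_parameters <- sum(vapply(ls(model$pars),
                                   function(n) length(model$pars[[n]]), 1))
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.epvs_segmodel <- function(x, ...) {
  cat(sprintf("epvs_segmodel: two-stage triple U-Net, %d input channels, %d base channels, %s trainable parameters\n",
              x$cfg$in_channels, x$cfg$base_channels,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# F-beta loss

#' F-beta overlap loss
#'
#' `1 - ((1 + beta) * sum(y * yhat) + eps) / (beta * sum(y) + sum(yhat) + eps)`.
#' With beta > 1 the loss rewards recall, with beta < 1 precision. It is 0
#' for a perfect binary prediction (including the all-empty case, where the
#' epsilon regularizer makes the ratio 1) and is always < 1.
#'
#' @param y binary label patch (0/1).
#' @param yhat probability patch in `[0, 1]`, same shape.
#' @param beta positive trade-off parameter.
#' @param epsilon stabilizer (default 1e-3).
#' @return scalar loss.
#' @export
fbeta_loss <- function(y, yhat, beta, epsilon = 1e-3) {
  if (length(y) != length(yhat)) stop("y and yhat shapes differ")
  if (beta <= 0) stop("beta must be positive")
  num <- (1 + beta) * sum(y * yhat) + epsilon
  den <- beta * sum(y) + sum(yhat) + epsilon
  1 - num / den
}

# gradient of fbeta_loss w.r.t. yhat
fbeta_grad <- function(y, yhat, beta, epsilon = 1e-3) {
  num <- (1 + beta) * sum(y * yhat) + epsilon
  den <- beta * sum(y) + sum(yhat) + epsilon
  -((1 + beta) * y * den - num) / den^2
}

#' Combined loss of the three heads
#'
#' Unweighted sum of the three F-beta losses: beta = 10 for the
#' recall-oriented stage-1 head, 0.1 for the precision-oriented one, 1 for
#' the stage-2 head.
#'
#' @param y binary label patch.
#' @param yhatA,yhatB,yhatC probability patches from the three heads.
#' @param config a [network_config()] carrying `betas` and `epsilon`.
#' @return scalar total loss in `[0, 3)`.
#' @export
total_loss <- function(y, yhatA, yhatB, yhatC, config = network_config()) {
  fbeta_loss(y, yhatA, config$betas[1], config$epsilon) +
    fbeta_loss(y, yhatB, config$betas[2], config$epsilon) +
    fbeta_loss(y, yhatC, config$betas[3], config$epsilon)
}

# ---------------------------------------------------------------------------
# whole-volume inference

#' Assemble the 19-channel network input
#'
#' Concatenates the normalized image, the 12 PCA feature maps, the white
#' matter mask and the five lobar indicator masks into the network's input
#' stack.
#'
#' @param vol normalized [epvs_volume()].
#' @param pca_stack `epvs_stack` of PCA maps (12 in the default pipeline).
#' @param wm_mask white-matter [epvs_mask()].
#' @param atlas an [epvs_atlas()].
#' @return an `epvs_stack` with `1 + n_pca + 1 + 5` maps.
#' @export
network_inputs <- function(vol, pca_stack, wm_mask, atlas) {
  stop_if_grid_mismatch(vol, wm_mask, "volume and WM mask")
  stop_if_grid_mismatch(vol, atlas, "volume and atlas")
  if (!identical(pca_stack$dims, dim(vol$grid)))
    stop("PCA stack not on the image grid")
  lobes <- vapply(1:5, function(l) as.numeric(atlas$grid == l),
                  numeric(length(vol$grid)))
  data <- cbind(as.numeric(vol$grid), pca_stack$data,
                as.numeric(wm_mask$grid), lobes)
  new_stack(data,
            c("image", pca_stack$names, "wm",
              names(epvs_regions())[-1]),
            dim(vol$grid), vol$geometry)
}

reflect_index <- function(n, m) {
  # indices 1..m reflected into 1..n (half-sample symmetric)
  i <- seq_len(m) - 1L
  p <- i %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Sliding-window whole-volume inference
#'
#' Tiles the volume with overlapping patches, runs the deterministic
#' forward pass (DropConnect off, batch-norm running statistics), and
#' averages the stage-2 head probabilities over all windows covering each
#' voxel. Volumes smaller than the patch are reflect-padded, predicted and
#' cropped.
#'
#' @param model an `epvs_segmodel`.
#' @param inputs `epvs_stack` with `in_channels` maps
#'   (see [network_inputs()]).
#' @param patch_size integer length-3, each divisible by 8.
#' @param overlap_fraction fraction of patch overlap between windows
#'   (default 0.5).
#' @return an `epvs_volume` probability map with values in `[0, 1]`.
#' @export
predict_volume <- function(model, inputs, patch_size = c(64L, 64L, 24L),
                           overlap_fraction = 0.5) {
  patch_size <- as.integer(patch_size)
  if (any(patch_size %% 2^model$cfg$n_downsamplings != 0))
    stop("patch size must be divisible by the total downsampling factor")
  dims <- inputs$dims
  pad_to <- pmax(dims, patch_size)
  idx <- lapply(1:3, function(a) reflect_index(dims[a], pad_to[a]))
  X <- inputs$data
  full <- array(0, c(pad_to, ncol(X)))
  for (c in seq_len(ncol(X)))
    full[, , , c] <- array(X[, c], dims)[idx[[1]], idx[[2]], idx[[3]]]
  acc <- array(0, pad_to)
  cnt <- array(0, pad_to)
  stride <- pmax(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  starts <- lapply(1:3, function(a) {
    s <- unique(c(seq(1L, pad_to[a] - patch_size[a] + 1L, by = stride[a]),
                  pad_to[a] - patch_size[a] + 1L))
    s
  })
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    rx <- sx:(sx + patch_size[1] - 1L)
    ry <- sy:(sy + patch_size[2] - 1L)
    rz <- sz:(sz + patch_size[3] - 1L)
    xp <- matrix(full[rx, ry, rz, ], prod(patch_size), ncol(X))
    attr(xp, "dims") <- patch_size
    fw <- forward_triple(model, xp, training = FALSE)
    acc[rx, ry, rz] <- acc[rx, ry, rz] + array(fw$pC, patch_size)
    cnt[rx, ry, rz] <- cnt[rx, ry, rz] + 1
  }
  prob <- (acc / cnt)[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])]
  epvs_volume(pmin(pmax(prob, 0), 1), inputs$geometry)
}
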