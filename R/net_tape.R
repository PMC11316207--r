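## A minimal dynamic reverse-mode tape over the C++ layer kernels.
##
## Values are (nvox x channels) matrices carrying a "dims" attribute (the
## spatial extent) and an integer node "id". Every op records a backward
## closure; backprop() walks the ops in reverse, accumulating gradients by
## node id (skip connections re-use values, so accumulation matters) and
## collecting parameter gradients by name into tape$pgrad.

tape_new <- function(model, training = FALSE) {
  T <- new.env(parent = emptyenv())
  T$model <- model
  T$training <- isTRUE(training)
  T$ops <- vector("list", 512)
  T$nops <- 0L
  T$next_id <- 0L
  T$pgrad <- list()
  T
}

tp_val <- function(T, x, dims, needs_grad = TRUE) {
  T$next_id <- T$next_id + 1L
  attr(x, "dims") <- as.integer(dims)
  attr(x, "id") <- T$next_id
  attr(x, "ng") <- needs_grad
  x
}

needs_grad <- function(x) isTRUE(attr(x, "ng"))

tp_record <- function(T, out_id, in_ids, bw) {
  T$nops <- T$nops + 1L
  if (T$nops > length(T$ops)) T$ops <- c(T$ops, vector("list", length(T$ops)))
  T$ops[[T$nops]] <- list(out = out_id, ins = in_ids, bw = bw)
}

# seeds: named list id -> gradient matrix
backprop <- function(T, seeds) {
  grads <- vector("list", T$next_id)
  for (nm in names(seeds)) grads[[as.integer(nm)]] <- seeds[[nm]]
  for (i in rev(seq_len(T$nops))) {
    op <- T$ops[[i]]
    g <- grads[[op$out]]
    if (is.null(g)) next
    gin <- op$bw(g)
    grads[op$out] <- list(NULL)      # free memory as we go
    for (k in seq_along(op$ins)) {
      id <- op$ins[k]
      if (is.null(gin[[k]])) next
      grads[[id]] <- if (is.null(grads[[id]])) gin[[k]]
                     else grads[[id]] + gin[[k]]
    }
  }
  invisible(T$pgrad)
}

acc_pgrad <- function(T, name, g) {
  T$pgrad[[name]] <- if (is.null(T$pgrad[[name]])) g else T$pgrad[[name]] + g
}

# lazily create a parameter (He initialization for conv kernels); shapes are
# fixed on the first forward pass, which build_model() runs under the
# model's seed.
get_param <- function(model, name, init) {
  p <- get0(name, envir = model$pars, inherits = FALSE)
  if (is.null(p)) {
    p <- init()
    model$pars[[name]] <- p
  }
  p
}

op_conv3 <- function(T, x, name) {
  model <- T$model
  dims <- attr(x, "dims")
  Cin <- ncol(x)
  Cout <- model$shape_hint[[name]] %||% model$cfg$base_channels
  W <- get_param(model, paste0(name, ".W"), function() {
    model$kind[[paste0(name, ".W")]] <- "convW"
    matrix(rnorm(27 * Cin * Cout, sd = sqrt(2 / (27 * Cin))), 27 * Cin, Cout)
  })
  b <- get_param(model, paste0(name, ".b"), function() {
    model$kind[[paste0(name, ".b")]] <- "bias"
    numeric(Cout)
  })
  p <- model$cfg$dropconnect_p
  if (T$training && p > 0) {
    dc <- cpp_dropconnect(W, p)
    Weff <- dc$Weff
    mask <- dc$mask_scaled
  } else {
    mask <- NULL
    Weff <- W
  }
  need_gx <- needs_grad(x)
  # single-precision GEMMs by default; double precision available for
  # numerical verification (options(epvseg.precision = "double"))
  dbl <- identical(getOption("epvseg.precision", "single"), "double")
  fw_fun <- if (dbl) cpp_conv3_fw_d else cpp_conv3_fw
  bw_fun <- if (dbl) cpp_conv3_bw_d else cpp_conv3_bw
  out <- tp_val(T, fw_fun(x, dims, Weff, b), dims)
  xin <- x
  tp_record(T, attr(out, "id"), attr(x, "id"), function(g) {
    bw <- bw_fun(xin, dims, Weff, g, need_gx)
    gW <- if (is.null(mask)) bw$gW else bw$gW * mask
    acc_pgrad(T, paste0(name, ".W"), gW)
    acc_pgrad(T, paste0(name, ".b"), as.numeric(bw$gb))
    list(bw$gx)
  })
  out
}

op_conv1 <- function(T, x, name, Cout = 1L) {
  model <- T$model
  Cin <- ncol(x)
  W <- get_param(model, paste0(name, ".W"), function() {
    model$kind[[paste0(name, ".W")]] <- "convW"
    matrix(rnorm(Cin * Cout, sd = sqrt(2 / Cin)), Cin, Cout)
  })
  b <- get_param(model, paste0(name, ".b"), function() {
    model$kind[[paste0(name, ".b")]] <- "bias"
    # sigmoid heads start at the sparse-foreground prior, not at 0.5
    rep(model$cfg$head_bias_init %||% 0, Cout)
  })
  p <- model$cfg$dropconnect_p
  if (T$training && p > 0) {
    dc <- cpp_dropconnect(W, p)
    Weff <- dc$Weff
    mask <- dc$mask_scaled
  } else {
    mask <- NULL
    Weff <- W
  }
  out <- tp_val(T, sweep(x %*% Weff, 2, b, "+"), attr(x, "dims"))
  xin <- x
  tp_record(T, attr(out, "id"), attr(x, "id"), function(g) {
    gW <- crossprod(xin, g)
    if (!is.null(mask)) gW <- gW * mask
    acc_pgrad(T, paste0(name, ".W"), gW)
    acc_pgrad(T, paste0(name, ".b"), colSums(g))
    list(g %*% t(Weff))
  })
  out
}

op_relu <- function(T, x) {
  out <- tp_val(T, pmax(x, 0), attr(x, "dims"))
  pos <- x > 0
  tp_record(T, attr(out, "id"), attr(x, "id"), function(g) list(g * pos))
  out
}

op_bn <- function(T, x, name, momentum = 0.1, eps = 1e-5) {
  model <- T$model
  C <- ncol(x)
  gamma <- get_param(model, paste0(name, ".g"), function() {
    model$kind[[paste0(name, ".g")]] <- "bn"
    rep(1, C)
  })
  beta <- get_param(model, paste0(name, ".s"), function() {
    model$kind[[paste0(name, ".s")]] <- "bn"
    rep(0, C)
  })
  bk <- paste0(name, ".running")
  rb <- get0(bk, envir = model$buffers, inherits = FALSE)
  if (is.null(rb)) rb <- list(mean = rep(0, C), var = rep(1, C))
  if (T$training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    model$buffers[[bk]] <- list(mean = (1 - momentum) * rb$mean + momentum * mu,
                                var = (1 - momentum) * rb$var + momentum * v)
  } else {
    mu <- rb$mean
    v <- rb$var
  }
  invstd <- 1 / sqrt(v + eps)
  fw <- cpp_bn_fw(x, mu, invstd, gamma, beta)
  xhat <- fw$xhat
  out <- tp_val(T, fw$out, attr(x, "dims"))
  training <- T$training
  tp_record(T, attr(out, "id"), attr(x, "id"), function(g) {
    bw <- cpp_bn_bw(g, xhat, invstd, gamma, training)
    acc_pgrad(T, paste0(name, ".g"), as.numeric(bw$dgamma))
    acc_pgrad(T, paste0(name, ".s"), as.numeric(bw$dbeta))
    list(bw$gx)
  })
  out
}

op_pool <- function(T, x, f) {
  dims <- attr(x, "dims")
  if (any(dims %% f != 0))
    stop(sprintf("patch extent %s not divisible by pooling factor %d; choose a patch size compatible with the downsampling factor",
                 paste(dims, collapse = "x"), f))
  fw <- cpp_maxpool_fw(x, dims, f)
  ng <- needs_grad(x)
  out <- tp_val(T, fw$out, dims %/% f, needs_grad = ng)
  nin <- nrow(x)
  tp_record(T, attr(out, "id"), attr(x, "id"), function(g) {
    if (!ng) return(list(NULL))
    list(cpp_maxpool_bw(g, fw$argmax, nin))
  })
  out
}

op_up2 <- function(T, x) {
  dims <- attr(x, "dims")
  out <- tp_val(T, cpp_upsample_fw(x, dims, 2L), dims * 2L)
  tp_record(T, attr(out, "id"), attr(x, "id"),
            function(g) list(cpp_upsample_bw(g, dims, 2L)))
  out
}

op_concat <- function(T, ...) {
  xs <- list(...)
  out <- tp_val(T, do.call(cbind, xs), attr(xs[[1]], "dims"))
  ncols <- vapply(xs, ncol, 1L)
  ids <- vapply(xs, function(x) attr(x, "id"), 1L)
  ngs <- vapply(xs, needs_grad, TRUE)
  tp_record(T, attr(out, "id"), ids, function(g) {
    off <- cumsum(c(0L, ncols))
    lapply(seq_along(ncols), function(k) {
      if (!ngs[k]) return(NULL)
      g[, (off[k] + 1):off[k + 1], drop = FALSE]
    })
  })
  out
}

op_sigmoid <- function(T, x) {
  s <- 1 / (1 + exp(-x))
  out <- tp_val(T, s, attr(x, "dims"))
  tp_record(T, attr(out, "id"), attr(x, "id"),
            function(g) list(g * s * (1 - s)))
  out
}
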