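# Shared fixtures, built once per test run.

# small phantom with a moderate EPVS load (48 x 48 x 24 at default spacing)
small_phantom_config <- function(...) {
  args <- list(...)
  base <- list(shape = c(48L, 48L, 24L),
               region_counts = c(frontal = 8L, parietal = 5L,
                                 temporal = 3L, occipital = 2L,
                                 basal_ganglia = 5L))
  do.call(phantom_config, utils::modifyList(base, args))
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  v <- get0(name, envir = .fixture_env, inherits = FALSE)
  if (is.null(v)) {
    v <- make()
    assign(name, v, envir = .fixture_env)
  }
  v
}

small_phantom <- function() fixture("small_phantom", function() {
  p <- make_phantom(small_phantom_config(), seed = 42L)
  p$id <- "P01"
  p
})

small_subject <- function() fixture("small_subject", function() {
  prepare_subject(small_phantom())
})

# a tiny volume with a straight bright tube along a given axis
tube_volume <- function(shape = c(24L, 24L, 12L),
                        spacing = c(0.6, 0.6, 1.5),
                        axis = 1L, radius_mm = 1.0, contrast = 2) {
  geom <- voxel_geometry(spacing)
  ctr <- (shape / 2) * spacing
  co <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
  X <- array(rep(co[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(co[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(co[[3]], each = shape[1] * shape[2]), shape)
  d2 <- switch(axis,
               `1` = (Y - ctr[2])^2 + (Z - ctr[3])^2,
               `2` = (X - ctr[1])^2 + (Z - ctr[3])^2,
               `3` = (X - ctr[1])^2 + (Y - ctr[2])^2)
  epvs_volume(1 + (contrast - 1) * exp(-d2 / (2 * radius_mm^2)), geom)
}

# independent grayscale morphology oracle: explicit min-then-max loops
tophat_oracle <- function(vol, radius_mm) {
  sp <- vol$geometry$spacing_mm
  d <- dim(vol$grid)
  r <- floor(radius_mm / sp)
  off <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  keep <- sqrt((off$x * sp[1])^2 + (off$y * sp[2])^2 +
                 (off$z * sp[3])^2) <= radius_mm + 1e-9
  off <- off[keep, ]
  run <- function(g, f) {
    out <- array(0, d)
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      xs <- x + off$x; ys <- y + off$y; zs <- z + off$z
      ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3]
      out[x, y, z] <- f(g[cbind(xs[ok], ys[ok], zs[ok])])
    }
    out
  }
  vol$grid - run(run(vol$grid, min), max)
}

# independent flood-fill component labelling (R implementation)
cc_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6L) nb <- nb[rowSums(abs(nb)) == 1, ]
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)[1, ]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        li <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# independent re-implementation of the ordinal binning rule, straight from
# its verbal definition (loop-based, no shared code)
binning_oracle <- function(count, counts, kind) {
  s <- sort(counts)
  p50 <- s[max(1, ceiling(0.5 * length(s)))]
  p75 <- s[max(1, ceiling(0.75 * length(s)))]
  width <- (p75 - p50) / 3
  upper_level <- function(x) {
    if (p75 <= p50) return(1L)
    if (x > p75) return(4L)
    for (i in 1:3) if (x <= p50 + i * width) return(i)
    4L
  }
  vapply(count, function(x) {
    if (kind == "lobar") {
      if (x <= p50) as.integer(x) else as.integer(p50 + upper_level(x))
    } else {
      if (x <= p50) {
        if (p50 == 0) 1L
        else as.integer(min(4, max(1, ceiling(4 * x / p50))))
      } else as.integer(4L + upper_level(x))
    }
  }, integer(1))
}
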