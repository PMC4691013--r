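# internal helpers: array shifting, separable filters, RNG scoping

.vol_dims <- function(x) {
  if (is(x, "SegmentationMask")) dim(x@labels) else dim(x@values)
}

.check_grid <- function(a, b, what = "volumes") {
  if (!identical(.vol_dims(a), .vol_dims(b)))
    stop("mismatched grids: ", what, " have different dimensions")
  if (abs(a@spacing - b@spacing) > 1e-9 * max(a@spacing, b@spacing))
    stop("mismatched grids: ", what, " have different voxel spacings")
  invisible(TRUE)
}

# shift a 3D array by `by` voxels along `axis`, zero padding
.shift_axis <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  n <- d[axis]
  if (abs(by) >= n) return(array(0, d))
  out <- array(0, d)
  dst <- src <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (by + 1L):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# separable 3-tap filter (w, 1-2w, w) applied along all three axes
.smooth_3tap <- function(a, w) {
  out <- a
  for (axis in 1:3) {
    out <- (1 - 2 * w) * out +
      w * .shift_axis(out, axis, 1L) +
      w * .shift_axis(out, axis, -1L)
  }
  out
}

# separable Gaussian smoothing, sd in voxels, zero padding
.smooth_gaussian <- function(a, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-r, r), sd = sd)
  k <- k / sum(k)
  out <- a
  for (axis in 1:3) {
    acc <- array(0, dim(a))
    for (t in seq_along(k))
      acc <- acc + k[t] * .shift_axis(out, axis, t - 1L - r)
    out <- acc
  }
  out
}

# evaluate expr with a scoped RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# physical voxel-centre coordinate arrays in (z, y, x) order
.grid_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  iz <- origin[1] + spacing * (seq_len(shape[1]) - 1)
  iy <- origin[2] + spacing * (seq_len(shape[2]) - 1)
  ix <- origin[3] + spacing * (seq_len(shape[3]) - 1)
  list(
    z = array(iz, shape),
    y = array(rep(iy, each = shape[1]), shape),
    x = array(rep(ix, each = shape[1] * shape[2]), shape)
  )
}

.key_value_lines <- function(x) {
  vapply(names(x), function(nm) {
    v <- x[[nm]]
    paste0(nm, " = ", paste(format(v, digits = 10), collapse = " "))
  }, "")
}
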