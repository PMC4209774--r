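#' Slice stacks and intensity volumes
#'
#' A `slice_stack` is an ordered list of 2D images (grayscale matrices or
#' h x w x 3 RGB arrays, intensities on the 0--255 scale) sharing one shape,
#' together with the physical voxel size.  A `gray_volume` is the scalar 3D
#' intensity field all texture extractors consume; its `data` array is
#' indexed `[z, y, x]` (slice, row, column), 0--255, finite.  A
#' `quantized_volume` holds integer gray-level bins in `0 .. G-1`.
#'
#' The default voxel size (0.34, 0.34, 0.5) micrometres reflects typical
#' confocal sampling: finer in-plane than axially.
#'
#' @param slices list of 2D matrices or h x w x 3 arrays, identical shapes,
#'   at least two; list order defines increasing z.
#' @param voxel_size numeric length-3, `(x, y, z)` extent of one voxel in
#'   micrometres, all positive.
#' @param source_id free-text provenance tag.
#' @return `slice_stack()` returns an object of class `"slice_stack"`.
#' @export
slice_stack <- function(slices, voxel_size = c(0.34, 0.34, 0.5),
                        source_id = "") {
  if (!is.list(slices) || length(slices) < 2L)
    stop_voxtex("a slice stack needs at least 2 slices",
                "voxtex_error_too_few_slices")
  shp <- lapply(slices, dim)
  ref <- shp[[1]]
  if (is.null(ref) || !(length(ref) %in% c(2L, 3L)))
    stop_voxtex("slices must be 2D matrices or h x w x channels arrays",
                "voxtex_error_bad_slice")
  same <- vapply(shp, function(d) identical(d, ref), logical(1))
  if (!all(same))
    stop_voxtex(sprintf("inconsistent slice shapes (slice %d differs from slice 1)",
                        which(!same)[1]),
                "voxtex_error_inconsistent_shapes")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(slices = slices,
                 voxel_size = as.numeric(voxel_size),
                 source_id = source_id),
            class = "slice_stack")
}

#' @param data 3D numeric array indexed `[z, y, x]`.
#' @rdname slice_stack
#' @export
gray_volume <- function(data, voxel_size = c(0.34, 0.34, 0.5)) {
  d <- dim(data)
  if (length(d) != 3L)
    stop_voxtex("gray_volume data must be a 3D array [z, y, x]",
                "voxtex_error_bad_volume")
  if (any(d < 2L))
    stop_voxtex("all three volume dimensions must be >= 2",
                "voxtex_error_bad_volume")
  if (!all(is.finite(data)))
    stop_voxtex("volume contains non-finite values", "voxtex_error_bad_volume")
  if (min(data) < 0 || max(data) > 255)
    stop_voxtex("volume intensities must lie in [0, 255]",
                "voxtex_error_bad_volume")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "gray_volume")
}

#' @param G number of gray-level bins, `>= 2`.
#' @rdname slice_stack
#' @export
quantized_volume <- function(data, G) {
  if (!is_count(G) || G < 2)
    stop_voxtex("G must be an integer >= 2", "voxtex_error_bad_gray_levels")
  d <- dim(data)
  if (length(d) != 3L)
    stop_voxtex("quantized_volume data must be a 3D array [z, y, x]",
                "voxtex_error_bad_volume")
  if (any(data < 0) || any(data > G - 1) || any(data != round(data)))
    stop_voxtex("quantized voxels must be integers in [0, G-1]",
                "voxtex_error_bad_volume")
  structure(list(data = data, G = as.integer(G)), class = "quantized_volume")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("slice_stack: %d slices of %d x %d%s, voxel (%.3g, %.3g, %.3g) um\n",
              length(x$slices), d[1], d[2],
              if (length(d) == 3L) sprintf(" x %d channels", d[3]) else "",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("gray_volume: %d x %d x %d (z, y, x), range [%.4g, %.4g], voxel (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], min(x$data), max(x$data),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
print.quantized_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("quantized_volume: %d x %d x %d (z, y, x), G = %d\n",
              d[1], d[2], d[3], x$G))
  invisible(x)
}

#' Collapse an RGB slice stack to a grayscale intensity volume
#'
#' Propidium-iodide fluorescence emits in the red band, so the default
#' policy keeps the red channel; `luminance` applies the Rec.601 weights
#' 0.299 R + 0.587 G + 0.114 B.  Grayscale stacks pass through unchanged
#' under any policy.
#'
#' @param stack a [slice_stack()].
#' @param channel_policy one of `"red"`, `"luminance"`, `"green"`, `"blue"`.
#' @return a [gray_volume()] with `data[z, y, x]`.
#' @export
rgb_to_gray <- function(stack, channel_policy = c("red", "luminance",
                                                  "green", "blue")) {
  stopifnot(inherits(stack, "slice_stack"))
  channel_policy <- tryCatch(match.arg(channel_policy),
    error = function(e) stop_voxtex(
      sprintf("unknown channel policy '%s'", channel_policy[1]),
      "voxtex_error_bad_policy"))
  to_gray <- function(sl) {
    if (is.matrix(sl)) return(sl)
    switch(channel_policy,
           red = sl[, , 1],
           green = sl[, , 2],
           blue = sl[, , 3],
           luminance = 0.299 * sl[, , 1] + 0.587 * sl[, , 2] + 0.114 * sl[, , 3])
  }
  g <- lapply(stack$slices, to_gray)
  nz <- length(g); ny <- nrow(g[[1]]); nx <- ncol(g[[1]])
  vol <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) vol[k, , ] <- g[[k]]
  gray_volume(vol, stack$voxel_size)
}

#' Slice-wise bilateral filtering
#'
#' Each z-slice is filtered independently (no inter-slice mixing) with the
#' classic bilateral kernel: the output at pixel p is the average of the
#' window around p, weighted by a spatial Gaussian of the pixel distance and
#' a range Gaussian of the intensity difference.  Edges are therefore
#' preserved while flat regions are smoothed.  Window pixels falling outside
#' the slice are simply dropped from the average (renormalised truncation).
#'
#' @param vol a [gray_volume()].
#' @param sigma_spatial spatial Gaussian standard deviation, pixels (> 0).
#' @param sigma_range range Gaussian standard deviation, intensity units (> 0).
#' @param radius half-width of the square window, pixels (>= 1); the window
#'   is `(2 radius + 1)^2`.
#' @return a filtered [gray_volume()] clipped to \[0, 255\].
#' @export
bilateral_filter_slicewise <- function(vol, sigma_spatial = 2,
                                       sigma_range = 20, radius = 5L) {
  stopifnot(inherits(vol, "gray_volume"))
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop_voxtex("bilateral sigmas must be positive", "voxtex_error_bad_sigma")
  if (!is_count(radius) || radius < 1)
    stop_voxtex("radius must be an integer >= 1", "voxtex_error_bad_radius")
  v <- vol$data
  d <- dim(v); ny <- d[2]; nx <- d[3]
  num <- array(0, d)
  den <- array(0, d)
  inv2ss <- 1 / (2 * sigma_spatial^2)
  inv2sr <- 1 / (2 * sigma_range^2)
  r <- as.integer(radius)
  # One pass per window offset, vectorised over every voxel of the volume;
  # the z axis rides along untouched so slices never mix.
  for (dy in -r:r) {
    ys <- max(1, 1 - dy):min(ny, ny - dy)   # rows whose neighbour exists
    for (dx in -r:r) {
      xs <- max(1, 1 - dx):min(nx, nx - dx)
      ws <- exp(-(dy * dy + dx * dx) * inv2ss)
      centre <- v[, ys, xs, drop = FALSE]
      neigh  <- v[, ys + dy, xs + dx, drop = FALSE]
      w <- ws * exp(-(centre - neigh)^2 * inv2sr)
      num[, ys, xs] <- num[, ys, xs] + w * neigh
      den[, ys, xs] <- den[, ys, xs] + w
    }
  }
  out <- num / den
  out[out < 0] <- 0
  out[out > 255] <- 255
  gray_volume(out, vol$voxel_size)
}

#' In-plane block-mean downsampling
#'
#' Averages non-overlapping `factor x factor` blocks within each slice;
#' the z axis is untouched.  Block averaging is anti-aliased (it conserves
#' the global mean exactly), unlike plain decimation.  The in-plane voxel
#' size is scaled by `factor`.
#'
#' @param vol a [gray_volume()].
#' @param factor positive integer dividing both in-plane dimensions.
#' @return a [gray_volume()] of shape `nz x ny/factor x nx/factor`.
#' @export
downsample_xy <- function(vol, factor) {
  stopifnot(inherits(vol, "gray_volume"))
  if (!is_count(factor) || factor < 1)
    stop_voxtex("factor must be a positive integer", "voxtex_error_bad_factor")
  f <- as.integer(factor)
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  if (d[2] %% f != 0L || d[3] %% f != 0L)
    stop_voxtex(sprintf("factor %d does not divide in-plane dims %d x %d",
                        f, d[2], d[3]),
                "voxtex_error_nondivisible_factor")
  ny2 <- d[2] %/% f; nx2 <- d[3] %/% f
  # Average over the two block axes of a (z, fy, y', fx, x') reshape.
  a <- array(vol$data, dim = c(d[1], f, ny2, f, nx2))
  a <- aperm(a, c(2, 4, 1, 3, 5))           # (fy, fx, z, y', x')
  out <- colMeans(a, dims = 2)
  vs <- vol$voxel_size * c(f, f, 1)
  gray_volume(out, vs)
}

#' Quantize an intensity volume into G gray-level bins
#'
#' Bin assignment is `floor(v * G / 256)` clamped to `G - 1`, i.e. equal
#' 256/G-wide bins over the 0--255 scale; monotone non-decreasing in the
#' intensity.  Exact integer semantics: intensity 255 maps to bin `G - 1`,
#' and quantizing an already binned volume again with the same G is the
#' identity on the bin representative scale.
#'
#' @param vol a [gray_volume()].
#' @param G number of gray levels (2--256 is sensible; 64 keeps a 64 x 64
#'   co-occurrence matrix dense on typical stack sizes).
#' @return a [quantized_volume()].
#' @export
quantize_volume <- function(vol, G = 64L) {
  stopifnot(inherits(vol, "gray_volume"))
  if (!is_count(G) || G < 2)
    stop_voxtex("G must be an integer >= 2", "voxtex_error_bad_gray_levels")
  b <- floor(vol$data * G / 256)
  b[b > G - 1] <- G - 1
  quantized_volume(b, G)
}
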