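#' Orthonormal wavelet bases
#'
#' Returns the analysis filter pair for the Haar or Daubechies-2 basis.
#' The lowpass taps satisfy `sum(h^2) = 1`; the highpass is the quadrature
#' mirror `g[m] = (-1)^m h[L - 1 - m]`.  Haar has 2 taps `(1, 1)/sqrt(2)`;
#' DB2 has 4 taps `(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
#' (4 sqrt(2))`.
#'
#' @param name `"haar"` or `"db2"`.
#' @return a `"wavelet_basis"`: list with `name`, `lowpass`, `highpass`.
#' @export
wavelet_basis <- function(name = c("haar", "db2")) {
  name <- match.arg(name)
  h <- switch(name,
              haar = c(1, 1) / sqrt(2),
              db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
                (4 * sqrt(2)))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(list(name = name, lowpass = h, highpass = g),
            class = "wavelet_basis")
}

# Subband labels in their fixed index order; letter k is the filter
# (L = lowpass, H = highpass) applied along rows (y), columns (x), stack (z).
OCTBAND_NAMES <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

# Index of signal sample `idx` (0-based, possibly out of range) under the
# chosen boundary extension; returns a 0-based in-range index.
extend_index <- function(idx, n, extension) {
  if (extension == "periodic") return(idx %% n)
  # half-sample symmetric reflection: ... x1 x0 | x0 x1 ... xn-1 | xn-1 ...
  while (idx < 0L || idx >= n) {
    if (idx < 0L) idx <- -1L - idx
    if (idx >= n) idx <- 2L * n - 1L - idx
  }
  idx
}

# ceil(n/2) x n analysis operator for one filter: row k computes
# sum_m f[m] x[2k + m] under the boundary extension (0-based k).
dwt_operator <- function(n, filter, extension) {
  n_out <- ceiling(n / 2)
  A <- matrix(0, n_out, n)
  for (k in seq_len(n_out) - 1L) {
    for (m in seq_along(filter) - 1L) {
      src <- extend_index(2L * k + m, n, extension)
      A[k + 1L, src + 1L] <- A[k + 1L, src + 1L] + filter[m + 1L]
    }
  }
  A
}

#' One level of the 1D discrete wavelet transform
#'
#' Convolves the signal with the basis lowpass/highpass filters and keeps
#' every second output: `approx[k] = sum_m h[m] x[2k + m]` (0-based), with
#' out-of-range samples supplied by the boundary extension.  Output length
#' is `ceil(n / 2)`.  Periodic extension preserves orthonormality (exact
#' Parseval and perfect reconstruction) but requires an even length;
#' half-sample symmetric extension accepts any length >= 2.
#'
#' @param signal numeric vector, length >= 2.
#' @param basis a [wavelet_basis()].
#' @param extension `"symmetric"` (default) or `"periodic"`.
#' @return list with `approx` and `detail` coefficient vectors.
#' @export
dwt1d <- function(signal, basis = wavelet_basis("haar"),
                  extension = c("symmetric", "periodic")) {
  extension <- match.arg(extension)
  n <- length(signal)
  if (n < 2L)
    stop_voxtex("signal must have length >= 2", "voxtex_error_short_signal")
  if (extension == "periodic" && n %% 2L != 0L)
    stop_voxtex("periodic extension requires an even length",
                "voxtex_error_odd_periodic")
  H <- dwt_operator(n, basis$lowpass, extension)
  G <- dwt_operator(n, basis$highpass, extension)
  list(approx = as.numeric(H %*% signal),
       detail = as.numeric(G %*% signal))
}

# Apply the analysis operators along one axis of a 3D array; returns the
# lowpass and highpass halves.  axis: 1 = z (slices), 2 = y (rows),
# 3 = x (columns).
dwt_along_axis <- function(arr, axis, basis, extension) {
  d <- dim(arr)
  n <- d[axis]
  if (extension == "periodic" && n %% 2L != 0L)
    stop_voxtex(sprintf("periodic extension requires an even length along axis %d",
                        axis),
                "voxtex_error_odd_periodic")
  H <- dwt_operator(n, basis$lowpass, extension)
  G <- dwt_operator(n, basis$highpass, extension)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)          # axis runs down rows
  back <- order(perm)
  reshape <- function(res) {
    dd <- d; dd[axis] <- nrow(res)
    aperm(array(res, dim = dd[perm]), back)
  }
  list(low = reshape(H %*% m), high = reshape(G %*% m))
}

#' Level-1 3D wavelet octband decomposition (2D + 1D scheme)
#'
#' The 2D transform is applied slice by slice (rows, then columns), the
#' four resulting subband stacks are then transformed along z, yielding the
#' 8 octant subbands.  Band labels give the filter applied along each axis
#' in the order rows (y), columns (x), stack (z): `HLL` is highpass along
#' y and lowpass along x and z.  Band indices 1..8 map to
#' `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`.
#'
#' Because the transform is separable and all three 1D passes commute, the
#' 2D + 1D ordering equals a direct axis-by-axis 3D transform; the scheme
#' matters only when coefficient processing is inserted between stages
#' (none is here).
#'
#' @param vol a [gray_volume()] or a bare 3D array.
#' @param basis a [wavelet_basis()].
#' @param extension `"symmetric"` (default; any dims) or `"periodic"`
#'   (orthonormal; even dims only).
#' @return an `"octband"`: list with `bands` (named list of 8 3D arrays,
#'   all of shape `ceil(dim / 2)`), `basis`, `extension`.
#' @export
dwt3d_2d1d <- function(vol, basis = wavelet_basis("haar"),
                       extension = c("symmetric", "periodic")) {
  extension <- match.arg(extension)
  arr <- if (inherits(vol, "gray_volume")) vol$data else vol
  stopifnot(length(dim(arr)) == 3L)
  if (any(dim(arr)[2:3] < length(basis$lowpass)))
    stop_voxtex("in-plane dimensions must be >= the filter length",
                "voxtex_error_short_signal")
  # 2D stage, per slice: rows (y) then columns (x).
  y <- dwt_along_axis(arr, 2L, basis, extension)
  LL <- dwt_along_axis(y$low, 3L, basis, extension)
  HL <- dwt_along_axis(y$high, 3L, basis, extension)
  # 1D stage along z splits each of LL, LH, HL, HH in two.
  z <- lapply(list(LL = LL$low, LH = LL$high,
                   HL = HL$low, HH = HL$high),
              dwt_along_axis, axis = 1L, basis = basis, extension = extension)
  bands <- list(LLL = z$LL$low, LLH = z$LL$high,
                LHL = z$LH$low, LHH = z$LH$high,
                HLL = z$HL$low, HLH = z$HL$high,
                HHL = z$HH$low, HHH = z$HH$high)
  structure(list(bands = bands, basis = basis, extension = extension),
            class = "octband")
}

#' @export
print.octband <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("octband: 8 bands of %d x %d x %d, basis %s, %s extension\n",
              d[1], d[2], d[3], x$basis$name, x$extension))
  invisible(x)
}

#' Invert the level-1 octband decomposition
#'
#' Exact only for periodic extension on even dimensions, where every 1D
#' operator is orthonormal and inversion is its transpose.  Provided for
#' verification (perfect-reconstruction tests), not for the feature
#' pipeline.
#'
#' @param ob an `"octband"` from [dwt3d_2d1d()] with periodic extension.
#' @param dims integer dims `(z, y, x)` of the original volume.
#' @return the reconstructed 3D array.
#' @export
idwt3d_2d1d <- function(ob, dims) {
  stopifnot(inherits(ob, "octband"))
  if (ob$extension != "periodic")
    stop_voxtex("exact inversion requires periodic extension",
                "voxtex_error_odd_periodic")
  basis <- ob$basis
  inv_axis <- function(low, high, axis, n) {
    H <- dwt_operator(n, basis$lowpass, "periodic")
    G <- dwt_operator(n, basis$highpass, "periodic")
    perm <- c(axis, setdiff(1:3, axis))
    back <- order(perm)
    dl <- dim(low)
    ml <- matrix(aperm(low, perm), nrow = dl[axis])
    mh <- matrix(aperm(high, perm), nrow = dl[axis])
    res <- t(H) %*% ml + t(G) %*% mh
    dd <- dl; dd[axis] <- n
    aperm(array(res, dim = dd[perm]), back)
  }
  b <- ob$bands
  LL <- inv_axis(b$LLL, b$LLH, 1L, dims[1])
  LH <- inv_axis(b$LHL, b$LHH, 1L, dims[1])
  HL <- inv_axis(b$HLL, b$HLH, 1L, dims[1])
  HH <- inv_axis(b$HHL, b$HHH, 1L, dims[1])
  L <- inv_axis(LL, LH, 3L, dims[3])
  H <- inv_axis(HL, HH, 3L, dims[3])
  inv_axis(L, H, 2L, dims[2])
}

#' Subband energy and entropy
#'
#' `band_energy()` is the sum of squared coefficients.  `band_entropy()`
#' defaults to the literal accumulation `-sum(W^2 log2 W^2)` over nonzero
#' coefficients — a scale-dependent quantity that can be negative for
#' coefficients above 1 in magnitude.  With `normalize = TRUE` the squared
#' coefficients are first converted to a probability distribution
#' `p = W^2 / sum(W^2)` and the Shannon entropy `-sum p log2 p` (bits) is
#' returned instead.
#'
#' @param band numeric array of wavelet coefficients.
#' @param normalize use the normalized Shannon form.
#' @return a scalar.
#' @export
band_energy <- function(band) sum(band^2)

#' @rdname band_energy
#' @export
band_entropy <- function(band, normalize = FALSE) {
  w2 <- band^2
  w2 <- w2[w2 > 0]
  if (length(w2) == 0L) return(0)
  if (normalize) {
    p <- w2 / sum(w2)
    -sum(p * log2(p))
  } else {
    -sum(w2 * log2(w2))
  }
}

#' The 16 octband texture features of a volume
#'
#' Runs the level-1 2D + 1D decomposition and evaluates energy (`WEN_k`)
#' and entropy (`WET_k`) on each of the 8 subbands in band-index order
#' (1 = LLL ... 8 = HHH).  Features are computed on the real-valued
#' intensity volume; no gray-level quantization is involved.
#'
#' @inheritParams dwt3d_2d1d
#' @param entropy `"literal"` (default) or `"normalized"`, see
#'   [band_entropy()].
#' @param rescale divide intensities by 255 before transforming, so that
#'   all coefficients (and hence literal entropies) refer to a \[0, 1\]
#'   intensity scale.  Default keeps the native 0--255 scale.
#' @return named numeric vector `WEN_1..WEN_8, WET_1..WET_8`.
#' @export
wavelet_features <- function(vol, basis = wavelet_basis("haar"),
                             extension = c("symmetric", "periodic"),
                             entropy = c("literal", "normalized"),
                             rescale = FALSE) {
  extension <- match.arg(extension)
  entropy <- match.arg(entropy)
  arr <- if (inherits(vol, "gray_volume")) vol$data else vol
  if (rescale) arr <- arr / 255
  ob <- dwt3d_2d1d(arr, basis = basis, extension = extension)
  wen <- vapply(OCTBAND_NAMES, function(b) band_energy(ob$bands[[b]]),
                numeric(1))
  wet <- vapply(OCTBAND_NAMES, function(b)
    band_entropy(ob$bands[[b]], normalize = entropy == "normalized"),
    numeric(1))
  out <- c(wen, wet)
  names(out) <- c(paste0("WEN_", 1:8), paste0("WET_", 1:8))
  out
}

WAVELET_FEATURE_NAMES <- c(paste0("WEN_", 1:8), paste0("WET_", 1:8))
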