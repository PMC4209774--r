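#' The 13 non-redundant 3D displacement directions
#'
#' Of the 26 neighbours of a voxel, opposite displacements produce
#' transposed co-occurrence matrices and are redundant under symmetric pair
#' counting, leaving 13 canonical directions: the vectors of
#' \{-1, 0, 1\}^3 \\ \{0\} whose first nonzero component (in dx, dy, dz
#' order) is positive.
#'
#' @param distance positive integer scale factor applied to every vector.
#' @return an object of class `"direction_set"`: list with `vectors` (a
#'   13 x 3 integer matrix, columns dx, dy, dz) and `distance`.
#' @export
direction_set_13 <- function(distance = 1L) {
  if (!is_count(distance) || distance < 1)
    stop_voxtex("distance must be a positive integer", "voxtex_error_bad_distance")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(v) {
    nz <- which(v != 0)
    length(nz) > 0 && v[nz[1]] > 0
  })
  vecs <- g[keep, , drop = FALSE]
  ord <- order(vecs[, 1], vecs[, 2], vecs[, 3])
  structure(list(vectors = vecs[ord, , drop = FALSE] * as.integer(distance),
                 distance = as.integer(distance)),
            class = "direction_set")
}

#' 3D gray-level co-occurrence matrices
#'
#' `cooc_single_direction()` counts, for one displacement `d = (dx, dy, dz)`
#' in voxels, every ordered pair of gray-level bins `(v(p), v(p + d))` over
#' all voxels `p` whose displaced partner lies inside the volume; with
#' `symmetric = TRUE` (default) each pair is also counted in reverse, making
#' the count matrix symmetric.  `cooc_averaged()` builds one matrix per
#' direction, normalizes each to unit sum, and averages them element-wise
#' into the single G x G matrix from which texture features are computed
#' (`normalize = "after"` instead pools raw counts across directions and
#' normalizes once; directions then weigh in proportion to their valid-pair
#' counts).
#'
#' @param vol a [quantized_volume()].
#' @param d integer displacement `(dx, dy, dz)`; x runs along slice columns,
#'   y along slice rows, z across slices.
#' @param symmetric count each ordered pair in both orders.
#' @return a `"cooc3d"` object: `matrix` (G x G, zero-based bin labels),
#'   `G`, `normalized`, `n_directions`.
#' @export
cooc_single_direction <- function(vol, d, symmetric = TRUE) {
  stopifnot(inherits(vol, "quantized_volume"), length(d) == 3L)
  dims <- dim(vol$data)            # (z, y, x)
  d <- as.integer(round(d))
  if (abs(d[1]) > dims[3] - 1L || abs(d[2]) > dims[2] - 1L ||
      abs(d[3]) > dims[1] - 1L)
    stop_voxtex(sprintf("displacement (%d, %d, %d) exceeds volume extent",
                        d[1], d[2], d[3]),
                "voxtex_error_displacement_too_large")
  G <- vol$G
  m <- cooc_count_pairs(vol$data, d, G)
  if (symmetric) m <- m + t(m)
  structure(list(matrix = m, G = G, normalized = FALSE,
                 n_directions = 1L),
            class = "cooc3d")
}

# Count ordered co-occurrence pairs for displacement (dx, dy, dz) by
# cross-tabulating two shifted views of the volume.
cooc_count_pairs <- function(v, d, G) {
  dims <- dim(v)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  dx <- d[1]; dy <- d[2]; dz <- d[3]
  zs <- max(1, 1 - dz):min(nz, nz - dz)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  if (length(zs) < 1L || length(ys) < 1L || length(xs) < 1L)
    return(matrix(0, G, G))
  a <- v[zs, ys, xs]
  b <- v[zs + dz, ys + dy, xs + dx]
  counts <- tabulate(a * G + b + 1L, nbins = G * G)
  matrix(counts, nrow = G, ncol = G, byrow = TRUE)
}

#' @param dirs a [direction_set_13()] (or compatible `"direction_set"`).
#' @param normalize `"before"` (normalize each directional matrix, then
#'   average) or `"after"` (pool counts, normalize once).
#' @rdname cooc_single_direction
#' @export
cooc_averaged <- function(vol, dirs = direction_set_13(),
                          symmetric = TRUE,
                          normalize = c("before", "after")) {
  stopifnot(inherits(vol, "quantized_volume"), inherits(dirs, "direction_set"))
  normalize <- match.arg(normalize)
  n_dir <- nrow(dirs$vectors)
  if (n_dir < 1L)
    stop_voxtex("direction set is empty", "voxtex_error_empty_directions")
  G <- vol$G
  acc <- matrix(0, G, G)
  for (i in seq_len(n_dir)) {
    d <- dirs$vectors[i, ]
    m <- cooc_single_direction(vol, d, symmetric = symmetric)$matrix
    s <- sum(m)
    if (s == 0)
      stop_voxtex(sprintf("direction (%d, %d, %d) yields no valid voxel pairs",
                          d[1], d[2], d[3]),
                  "voxtex_error_degenerate_direction")
    acc <- acc + if (normalize == "before") m / s else m
  }
  out <- if (normalize == "before") acc / n_dir else acc / sum(acc)
  structure(list(matrix = out, G = G, normalized = TRUE,
                 n_directions = n_dir),
            class = "cooc3d")
}

#' @export
print.cooc3d <- function(x, ...) {
  cat(sprintf("cooc3d: %d x %d, %s, averaged over %d direction(s)\n",
              x$G, x$G, if (x$normalized) "normalized" else "raw counts",
              x$n_directions))
  invisible(x)
}

#' Marginal statistics of a normalized co-occurrence matrix
#'
#' With 1-based indices `i, j = 1..G` over the matrix `c(i, j)`:
#' `mu_x = M_x = sum_ij i c(i,j)`, `mu_y = M_y = sum_ij j c(i,j)`,
#' `sigma_x`, `sigma_y` the corresponding standard deviations, and the
#' sum-distribution `c_sum(k) = sum_{i+j=k} c(i,j)` for `k = 2..2G` with
#' its mean `mu_sum`.  These feed the correlation, cluster, and sum
#' features.
#'
#' @param m a normalized `"cooc3d"`.
#' @return list with `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `M_x`, `M_y`,
#'   `c_sum` (named vector over k = 2..2G), `mu_sum`.
#' @export
glcm_marginals <- function(m) {
  stopifnot(inherits(m, "cooc3d"))
  if (!isTRUE(m$normalized))
    stop_voxtex("marginals require a normalized co-occurrence matrix",
                "voxtex_error_unnormalized")
  G <- m$G
  cm <- m$matrix
  i <- matrix(rep(seq_len(G), G), G, G)        # row index
  j <- t(i)
  mu_x <- sum(i * cm); mu_y <- sum(j * cm)
  sigma_x <- sqrt(max(0, sum((i - mu_x)^2 * cm)))
  sigma_y <- sqrt(max(0, sum((j - mu_y)^2 * cm)))
  ks <- 2:(2 * G)
  c_sum <- vapply(ks, function(k) sum(cm[i + j == k]), numeric(1))
  names(c_sum) <- ks
  mu_sum <- sum(ks * c_sum)
  list(mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
       M_x = mu_x, M_y = mu_y, c_sum = c_sum, mu_sum = mu_sum)
}

#' The 12 co-occurrence texture features
#'
#' Haralick-style statistics of a normalized, direction-averaged 3D
#' co-occurrence matrix `c(i, j)`, `i, j = 1..G`:
#' \describe{
#'   \item{ASM}{angular second moment (energy), `sum c^2`}
#'   \item{ENTR}{entropy, `-sum c log c` (0 log 0 := 0)}
#'   \item{CORR}{correlation, `(sum i j c - mu_x mu_y) / (sigma_x sigma_y)`;
#'     `NaN` when either marginal is degenerate}
#'   \item{CONT}{contrast, `sum (i - j)^2 c`}
#'   \item{VAR}{variance, `sum (i - mu_x)^2 c`}
#'   \item{SM}{sum mean, `sum_k k c_sum(k)`}
#'   \item{SV}{sum variance, `sum_k (k - mu_sum)^2 c_sum(k)`}
#'   \item{CS}{cluster shade, `sum (i - M_x + j - M_y)^3 c`}
#'   \item{CT}{cluster tendency, `sum (i - M_x + j - M_y)^4 c`}
#'   \item{SIDM}{second-order inverse difference moment (homogeneity),
#'     `sum c / (1 + (i - j)^2)`}
#'   \item{PTP}{peak transition probability, `max c`}
#'   \item{SDM}{second-order diagonal moment, `sum 0.5 |i - j| c` by
#'     default; the signed variant `sum 0.5 (j - i) c` — identically zero
#'     on any symmetric matrix — is available with `sdm = "signed"`}
#' }
#'
#' @param m a normalized `"cooc3d"`.
#' @param log_base base of the entropy logarithm, `2` (default) or `exp(1)`.
#' @param sdm `"absolute"` (default) or `"signed"` diagonal moment.
#' @return named numeric vector of the 12 features, in the order
#'   `ASM, ENTR, CORR, CONT, VAR, SM, SV, CS, CT, SIDM, PTP, SDM`.
#' @export
glcm_features <- function(m, log_base = 2, sdm = c("absolute", "signed")) {
  stopifnot(inherits(m, "cooc3d"))
  sdm <- match.arg(sdm)
  if (!isTRUE(m$normalized))
    stop_voxtex("features require a normalized co-occurrence matrix",
                "voxtex_error_unnormalized")
  G <- m$G
  cm <- m$matrix
  mar <- glcm_marginals(m)
  i <- matrix(rep(seq_len(G), G), G, G)
  j <- t(i)
  pos <- cm > 0
  entr <- -sum(cm[pos] * log(cm[pos], base = log_base))
  corr <- if (mar$sigma_x * mar$sigma_y > 0)
    (sum(i * j * cm) - mar$mu_x * mar$mu_y) / (mar$sigma_x * mar$sigma_y)
  else NaN
  ks <- as.numeric(names(mar$c_sum))
  dev <- i - mar$M_x + j - mar$M_y
  c(ASM  = sum(cm^2),
    ENTR = entr,
    CORR = corr,
    CONT = sum((i - j)^2 * cm),
    VAR  = sum((i - mar$mu_x)^2 * cm),
    SM   = sum(ks * mar$c_sum),
    SV   = sum((ks - mar$mu_sum)^2 * mar$c_sum),
    CS   = sum(dev^3 * cm),
    CT   = sum(dev^4 * cm),
    SIDM = sum(cm / (1 + (i - j)^2)),
    PTP  = max(cm),
    SDM  = if (sdm == "absolute") sum(0.5 * abs(i - j) * cm)
           else sum(0.5 * (j - i) * cm))
}

# Canonical feature-name order used by feature tables and CSV output.
GLCM_FEATURE_NAMES <- c("ASM", "ENTR", "CORR", "CONT", "VAR", "SM", "SV",
                        "CS", "CT", "SIDM", "PTP", "SDM")
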