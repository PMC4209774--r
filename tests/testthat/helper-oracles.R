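# Independent reference implementations used to pin expected values.
# Deliberately written as naive explicit loops, sharing no code with the
# package internals they check.

# random integer-binned volume as a bare array, dims (z, y, x)
random_bins <- function(dims, G) {
  array(sample(0:(G - 1), prod(dims), replace = TRUE), dim = dims)
}

# Brute-force co-occurrence counts for displacement d = (dx, dy, dz):
# x runs along the 3rd (column) index, y along the 2nd, z along the 1st.
oracle_cooc_counts <- function(vol, d, G, symmetric = TRUE) {
  dims <- dim(vol)
  m <- matrix(0, G, G)
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[3])) {
      z2 <- z + d[3]; y2 <- y + d[2]; x2 <- x + d[1]
      if (z2 < 1 || z2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          x2 < 1 || x2 > dims[3]) next
      a <- vol[z, y, x] + 1; b <- vol[z2, y2, x2] + 1
      m[a, b] <- m[a, b] + 1
      if (symmetric) m[b, a] <- m[b, a] + 1
    }
  m
}

# normalize-each-then-average over a matrix of direction rows
oracle_cooc_avg <- function(vol, dirs, G) {
  acc <- matrix(0, G, G)
  for (i in seq_len(nrow(dirs))) {
    m <- oracle_cooc_counts(vol, dirs[i, ], G)
    acc <- acc + m / sum(m)
  }
  acc / nrow(dirs)
}

# All 12 co-occurrence features by scalar loops over the matrix cells.
oracle_glcm_features <- function(cm, log_base = 2) {
  G <- nrow(cm)
  asm <- 0; entr <- 0; cont <- 0; sidm <- 0; sdm <- 0
  mux <- 0; muy <- 0
  for (i in 1:G) for (j in 1:G) {
    mux <- mux + i * cm[i, j]; muy <- muy + j * cm[i, j]
  }
  sx2 <- 0; sy2 <- 0; varr <- 0; corr_num <- 0; cs <- 0; ct <- 0
  for (i in 1:G) for (j in 1:G) {
    c0 <- cm[i, j]
    asm <- asm + c0^2
    if (c0 > 0) entr <- entr - c0 * log(c0, base = log_base)
    cont <- cont + (i - j)^2 * c0
    sidm <- sidm + c0 / (1 + (i - j)^2)
    sdm <- sdm + 0.5 * abs(i - j) * c0
    sx2 <- sx2 + (i - mux)^2 * c0
    sy2 <- sy2 + (j - muy)^2 * c0
    varr <- varr + (i - mux)^2 * c0
    corr_num <- corr_num + i * j * c0
    cs <- cs + (i - mux + j - muy)^3 * c0
    ct <- ct + (i - mux + j - muy)^4 * c0
  }
  csum <- numeric(2 * G)
  for (i in 1:G) for (j in 1:G) csum[i + j] <- csum[i + j] + cm[i, j]
  sm <- 0
  for (k in 2:(2 * G)) sm <- sm + k * csum[k]
  sv <- 0
  for (k in 2:(2 * G)) sv <- sv + (k - sm)^2 * csum[k]
  corr <- if (sx2 > 0 && sy2 > 0)
    (corr_num - mux * muy) / sqrt(sx2 * sy2) else NaN
  c(ASM = asm, ENTR = entr, CORR = corr, CONT = cont, VAR = varr,
    SM = sm, SV = sv, CS = cs, CT = ct, SIDM = sidm, PTP = max(cm),
    SDM = sdm)
}

# One DWT step on a vector by direct convolution with periodic indexing.
oracle_dwt_step <- function(x, f) {
  n <- length(x)
  out <- numeric(n %/% 2)
  for (k in seq_along(out)) {
    s <- 0
    for (m in seq_along(f)) s <- s + f[m] * x[(2 * (k - 1) + m - 1) %% n + 1]
    out[k] <- s
  }
  out
}

# Separable full-3D tensor transform, axis by axis in the package's order
# (rows y, then columns x, then stack z), built on oracle_dwt_step only.
oracle_dwt3d <- function(arr, h, g) {
  split_axis <- function(a, axis) {
    d <- dim(a)
    lo_d <- d; lo_d[axis] <- d[axis] %/% 2
    lo <- array(0, lo_d); hi <- array(0, lo_d)
    idx <- function(z, y, x) c(z, y, x)
    others <- setdiff(1:3, axis)
    for (i in seq_len(d[others[1]])) for (j in seq_len(d[others[2]])) {
      sel <- as.list(rep(TRUE, 3)); sel[[others[1]]] <- i; sel[[others[2]]] <- j
      line <- do.call(`[`, c(list(a), sel))
      lo_line <- oracle_dwt_step(line, h)
      hi_line <- oracle_dwt_step(line, g)
      lo <- do.call(`[<-`, c(list(lo), sel, list(lo_line)))
      hi <- do.call(`[<-`, c(list(hi), sel, list(hi_line)))
    }
    list(lo, hi)
  }
  y <- split_axis(arr, 2)
  LL <- split_axis(y[[1]], 3); HL <- split_axis(y[[2]], 3)
  quads <- list(LL = LL[[1]], LH = LL[[2]], HL = HL[[1]], HH = HL[[2]])
  out <- list()
  for (nm in names(quads)) {
    z <- split_axis(quads[[nm]], 1)
    out[[paste0(nm, "L")]] <- z[[1]]
    out[[paste0(nm, "H")]] <- z[[2]]
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# Within/total scatter and Wilks' lambda by explicit double loops.
oracle_wilks <- function(X, g) {
  X <- as.matrix(X)
  p <- ncol(X)
  W <- matrix(0, p, p); Tm <- matrix(0, p, p)
  grand <- colMeans(X)
  for (cl in unique(g)) {
    Xi <- X[g == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) {
      dw <- Xi[r, ] - mi
      dt <- Xi[r, ] - grand
      W <- W + outer(dw, dw)
      Tm <- Tm + outer(dt, dt)
    }
  }
  det(W) / det(Tm)
}

# Direct per-pixel bilateral filter of one slice (double loop reference).
oracle_bilateral_slice <- function(img, sigma_s, sigma_r, radius) {
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (y in 1:ny) for (x in 1:nx) {
    num <- 0; den <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 < 1 || y2 > ny || x2 < 1 || x2 > nx) next
      w <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2)) *
        exp(-(img[y, x] - img[y2, x2])^2 / (2 * sigma_r^2))
      num <- num + w * img[y2, x2]
      den <- den + w
    }
    out[y, x] <- num / den
  }
  out
}

# Truncated-window Gaussian smoothing of one slice (the sigma_r -> Inf
# limit of the bilateral filter).
oracle_gaussian_slice <- function(img, sigma_s, radius) {
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (y in 1:ny) for (x in 1:nx) {
    num <- 0; den <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 < 1 || y2 > ny || x2 < 1 || x2 > nx) next
      w <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2))
      num <- num + w * img[y2, x2]
      den <- den + w
    }
    out[y, x] <- num / den
  }
  out
}

# Gaussian-class feature table: 4 grades, class means spaced `sep` apart
# on the first `n_signal` features, unit noise elsewhere.
toy_grade_table <- function(n_per = 8, p = 5, sep = 3, n_signal = 2,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(4 * n_per * p), 4 * n_per, p)
  grades <- rep(1:4, each = n_per)
  for (f in seq_len(min(n_signal, p)))
    X[, f] <- X[, f] + sep * grades * (1 + 0.2 * f)
  suppressWarnings(feature_table(X, paste0("f", seq_len(p)), grades))
}
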