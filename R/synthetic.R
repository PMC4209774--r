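#' Per-grade synthetic texture specifications
#'
#' Describes one grade's nucleus-like blob texture: Poisson-placed bright
#' ellipsoidal Gaussian blobs on a dark noisy background, blurred along z
#' to mimic optical sectioning anisotropy.  Nuclear grading is driven by
#' nucleus size, shape and chromatin content, so the knobs map directly:
#' blob radius (size), per-axis radial perturbation (shape irregularity),
#' blob density and speckle (content/heterogeneity).
#'
#' @param grade integer 1..4.
#' @param nucleus_density expected blobs per 1000 voxels.
#' @param radius_mean,radius_sd blob radius distribution, voxels.
#' @param intensity_mean,intensity_sd blob peak amplitude, 0--255 scale
#'   (must satisfy `intensity_mean + 3 intensity_sd <= 255`).
#' @param shape_irregularity radial perturbation amplitude in \[0, 1\];
#'   each axis of a blob is scaled by an independent
#'   `U(1 - a, 1 + a)` draw.
#' @param speckle_sd additive Gaussian voxel noise, intensity units.
#' @param background_level constant background, 0--255.
#' @param z_blur_sigma Gaussian blur along z, voxels.
#' @return a `"grade_texture_spec"`.
#' @export
grade_texture_spec <- function(grade, nucleus_density, radius_mean,
                               radius_sd, intensity_mean, intensity_sd,
                               shape_irregularity, speckle_sd,
                               background_level, z_blur_sigma) {
  stopifnot(grade %in% 1:4)
  vals <- c(nucleus_density, radius_mean, radius_sd, intensity_mean,
            intensity_sd, shape_irregularity, speckle_sd, background_level,
            z_blur_sigma)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_voxtex("all texture spec fields must be finite and non-negative",
                "voxtex_error_bad_spec")
  if (shape_irregularity > 1)
    stop_voxtex("shape_irregularity must lie in [0, 1]", "voxtex_error_bad_spec")
  if (intensity_mean + 3 * intensity_sd > 255)
    stop_voxtex("intensity_mean + 3 intensity_sd must be <= 255",
                "voxtex_error_bad_spec")
  structure(list(grade = as.integer(grade),
                 nucleus_density = nucleus_density,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 shape_irregularity = shape_irregularity,
                 speckle_sd = speckle_sd,
                 background_level = background_level,
                 z_blur_sigma = z_blur_sigma),
            class = "grade_texture_spec")
}

#' Default four-grade texture specifications
#'
#' Blob size, size spread, shape irregularity, density and speckle all
#' increase monotonically with grade, echoing how nuclear enlargement,
#' pleomorphism and chromatin coarseness progress; the four classes are
#' statistically distinguishable by both texture families.
#'
#' @return list of four [grade_texture_spec()]s, grades 1..4.
#' @export
default_grade_specs <- function() {
  list(
    grade_texture_spec(1, nucleus_density = 0.15, radius_mean = 2.5,
                       radius_sd = 0.4, intensity_mean = 150,
                       intensity_sd = 20, shape_irregularity = 0.05,
                       speckle_sd = 5, background_level = 20,
                       z_blur_sigma = 0.8),
    grade_texture_spec(2, nucleus_density = 0.30, radius_mean = 3.2,
                       radius_sd = 0.6, intensity_mean = 160,
                       intensity_sd = 22, shape_irregularity = 0.15,
                       speckle_sd = 10, background_level = 20,
                       z_blur_sigma = 0.8),
    grade_texture_spec(3, nucleus_density = 0.45, radius_mean = 4.0,
                       radius_sd = 0.9, intensity_mean = 170,
                       intensity_sd = 25, shape_irregularity = 0.30,
                       speckle_sd = 16, background_level = 20,
                       z_blur_sigma = 0.8),
    grade_texture_spec(4, nucleus_density = 0.65, radius_mean = 5.0,
                       radius_sd = 1.2, intensity_mean = 180,
                       intensity_sd = 25, shape_irregularity = 0.45,
                       speckle_sd = 24, background_level = 20,
                       z_blur_sigma = 0.8))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards (determinism without hidden global state).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic tissue-texture volume
#'
#' Blob count is Poisson with rate `nucleus_density x voxels / 1000`;
#' centres are uniform in the volume; each blob is an axis-aligned
#' ellipsoidal Gaussian profile with half-radius standard deviation (so
#' the nominal radius is about two sigma), per-axis radii perturbed by the
#' shape irregularity, and a truncated-normal peak amplitude.  Overlapping
#' blobs compose by maximum (nuclei occlude rather than add).  The blob
#' field is blurred along z, the background level and Gaussian speckle are
#' added, and the result is clipped to \[0, 255\].  Output is fully
#' determined by `seed`.
#'
#' @param spec a [grade_texture_spec()].
#' @param dims integer `(z, y, x)` volume shape, each >= 16.
#' @param seed integer RNG seed.
#' @param voxel_size passed through to the volume.
#' @return a [gray_volume()].
#' @export
generate_volume <- function(spec, dims = c(48L, 64L, 64L), seed = 1L,
                            voxel_size = c(0.34, 0.34, 0.5)) {
  stopifnot(inherits(spec, "grade_texture_spec"))
  if (length(dims) != 3L || any(dims < 16L))
    stop_voxtex("dims must be (z, y, x) with every extent >= 16",
                "voxtex_error_bad_dims")
  dims <- as.integer(dims)
  with_seed(seed, {
    vol <- array(0, dim = dims)
    n_blobs <- stats::rpois(1, spec$nucleus_density * prod(dims) / 1000)
    for (b in seq_len(n_blobs)) {
      centre <- stats::runif(3, min = 1, max = dims)        # (z, y, x)
      r <- max(0.8, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
      scales <- stats::runif(3, 1 - spec$shape_irregularity,
                             1 + spec$shape_irregularity)
      amp <- min(255, max(0, stats::rnorm(1, spec$intensity_mean,
                                          spec$intensity_sd)))
      sig <- pmax(0.4, r * scales / 2)                      # radius ~ 2 sigma
      ext <- ceiling(3 * sig)
      rng <- lapply(1:3, function(a)
        max(1L, floor(centre[a] - ext[a])):min(dims[a], ceiling(centre[a] + ext[a])))
      if (any(lengths(rng) == 0L)) next
      dz <- (rng[[1]] - centre[1]) / sig[1]
      dy <- (rng[[2]] - centre[2]) / sig[2]
      dx <- (rng[[3]] - centre[3]) / sig[3]
      prof <- amp * exp(-0.5 * (outer(outer(dz^2, dy^2, `+`), dx^2, `+`)))
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        pmax(vol[rng[[1]], rng[[2]], rng[[3]]], prof)
    }
    if (spec$z_blur_sigma > 0) vol <- blur_z(vol, spec$z_blur_sigma)
    vol <- vol + spec$background_level
    if (spec$speckle_sd > 0)
      vol <- vol + stats::rnorm(length(vol), sd = spec$speckle_sd)
    vol[vol < 0] <- 0
    vol[vol > 255] <- 255
    out <- gray_volume(vol, voxel_size)
    out$n_blobs <- n_blobs          # exposed for moment checks
    out
  })
}

# 1D Gaussian blur along the z (first) axis with edge replication.
blur_z <- function(vol, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  nz <- dim(vol)[1]
  out <- array(0, dim = dim(vol))
  for (m in -r:r) {
    src <- pmin(pmax(seq_len(nz) + m, 1L), nz)
    out <- out + k[m + r + 1L] * vol[src, , , drop = FALSE]
  }
  out
}

#' Cohort specification and generation
#'
#' `cohort_spec()` bundles the four grade specs with per-grade train/test
#' counts (defaults 4, 12, 7, 11 train and 4, 11, 6, 11 test — 34 + 32
#' volumes), the volume shape, and a master seed.  `generate_cohort()`
#' derives an independent per-volume seed from the master seed, grade and
#' within-grade index, so cohorts are reproducible and individual volumes
#' can be regenerated in isolation.
#'
#' @param per_grade_specs list of four [grade_texture_spec()]s.
#' @param n_train,n_test integer length-4 counts per grade, each >= 1.
#' @param dims volume shape `(z, y, x)`, each >= 16.
#' @param seed master seed.
#' @return `cohort_spec()`: a `"cohort_spec"`.  `generate_cohort()`: list
#'   with `train` and `test`, each a list of records
#'   `list(volume, grade, sample_id)`.
#' @export
cohort_spec <- function(per_grade_specs = default_grade_specs(),
                        n_train = c(4L, 12L, 7L, 11L),
                        n_test = c(4L, 11L, 6L, 11L),
                        dims = c(48L, 64L, 64L), seed = 1L) {
  stopifnot(length(per_grade_specs) == 4L,
            all(vapply(per_grade_specs, inherits, logical(1),
                       "grade_texture_spec")),
            length(n_train) == 4L, length(n_test) == 4L,
            all(n_train >= 1L), all(n_test >= 1L))
  if (length(dims) != 3L || any(dims < 16L))
    stop_voxtex("dims must be (z, y, x) with every extent >= 16",
                "voxtex_error_bad_dims")
  structure(list(per_grade_specs = per_grade_specs,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 dims = as.integer(dims), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @param cohort a `cohort_spec()`.
#' @rdname cohort_spec
#' @export
generate_cohort <- function(cohort = cohort_spec()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  make <- function(grade, idx, split) {
    seed <- mix_seed(cohort$seed, grade, idx)
    list(volume = generate_volume(cohort$per_grade_specs[[grade]],
                                  dims = cohort$dims, seed = seed),
         grade = grade,
         sample_id = sprintf("g%d_%s%02d", grade, split, idx))
  }
  train <- list(); test <- list()
  for (g in 1:4) {
    for (i in seq_len(cohort$n_train[g]))
      train[[length(train) + 1L]] <- make(g, i, "train")
    for (i in seq_len(cohort$n_test[g]))
      test[[length(test) + 1L]] <- make(g, cohort$n_train[g] + i, "test")
  }
  list(train = train, test = test)
}
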