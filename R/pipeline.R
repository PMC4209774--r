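#' Extract all three texture feature vectors from one volume
#'
#' Runs the standard per-volume chain: optional slice-wise bilateral
#' denoising, then (a) gray-level quantization, the 13-direction averaged
#' co-occurrence matrix and its 12 features, and (b) the 16 octband
#' energy/entropy features for each requested wavelet basis, computed on
#' the unquantized (post-filter) intensities.
#'
#' @param vol a [gray_volume()].
#' @param gray_levels co-occurrence gray levels G (default 64).
#' @param filter apply [bilateral_filter_slicewise()] first (default TRUE;
#'   set FALSE to extract from raw intensities).
#' @param sigma_spatial,sigma_range,radius bilateral parameters.
#' @param distance displacement distance in voxels for the direction set.
#' @param log_base co-occurrence entropy base.
#' @param extension,entropy,rescale wavelet options, see
#'   [wavelet_features()].
#' @param bases character vector of wavelet basis names.
#' @return named list: `glcm` (12 features), plus one 16-feature vector
#'   per basis (`haar`, `db2`).
#' @export
extract_texture_features <- function(vol, gray_levels = 64L, filter = TRUE,
                                     sigma_spatial = 2, sigma_range = 20,
                                     radius = 5L, distance = 1L,
                                     log_base = 2,
                                     extension = "symmetric",
                                     entropy = "literal", rescale = FALSE,
                                     bases = c("haar", "db2")) {
  stopifnot(inherits(vol, "gray_volume"))
  if (filter)
    vol <- bilateral_filter_slicewise(vol, sigma_spatial, sigma_range, radius)
  q <- quantize_volume(vol, gray_levels)
  m <- cooc_averaged(q, direction_set_13(distance))
  out <- list(glcm = glcm_features(m, log_base = log_base))
  for (b in bases)
    out[[b]] <- wavelet_features(vol, wavelet_basis(b),
                                 extension = extension, entropy = entropy,
                                 rescale = rescale)
  out
}

#' Texture feature tables for a generated cohort
#'
#' Extracts every volume once and assembles the three train/test table
#' pairs consumed by [run_all_configs()].
#'
#' @param cohort output of [generate_cohort()] (or any list with `train`
#'   and `test` lists of `list(volume, grade, sample_id)` records).
#' @param ... passed to [extract_texture_features()].
#' @return named list with elements `"wavelet-haar"`, `"wavelet-db2"`,
#'   `"glcm"`, each `list(train = , test = )` of [feature_table()]s.
#' @export
cohort_feature_tables <- function(cohort, ...) {
  extract_split <- function(records) {
    feats <- lapply(records, function(r)
      extract_texture_features(r$volume, ...))
    grades <- vapply(records, `[[`, integer(1), "grade")
    ids <- vapply(records, `[[`, character(1), "sample_id")
    one <- function(key) suppressWarnings(feature_table(
      do.call(rbind, lapply(feats, `[[`, key)),
      grades = grades, sample_ids = ids))
    list(glcm = one("glcm"), haar = one("haar"), db2 = one("db2"))
  }
  tr <- extract_split(cohort$train)
  te <- extract_split(cohort$test)
  list("wavelet-haar" = list(train = tr$haar, test = te$haar),
       "wavelet-db2" = list(train = tr$db2, test = te$db2),
       "glcm" = list(train = tr$glcm, test = te$glcm))
}

#' Run the full six-classifier grading study on a synthetic cohort
#'
#' Generates the cohort, extracts all texture features, and runs the six
#' classifier configurations.  This is the end-to-end entry point used by
#' the acceptance checks.
#'
#' @param cohort a [cohort_spec()] (defaults to the standard 34-train /
#'   32-test design at 64 x 64 x 48).
#' @param extraction list of arguments for [extract_texture_features()].
#' @param ... passed to [run_all_configs()] (alpha levels, pca_k, priors).
#' @return as [run_all_configs()], plus `tables` (the feature tables).
#' @export
grade_synthetic_cohort <- function(cohort = cohort_spec(),
                                   extraction = list(), ...) {
  vols <- generate_cohort(cohort)
  tables <- do.call(cohort_feature_tables, c(list(vols), extraction))
  res <- run_all_configs(tables, ...)
  res$tables <- tables
  res
}
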