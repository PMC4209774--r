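#' Samples-by-features tables with grade labels
#'
#' The interchange object between feature extraction and statistics: an
#' `n x p` numeric matrix with feature names, per-sample grade labels in
#' 1..4, and sample identifiers.
#'
#' @param values numeric matrix, samples in rows.
#' @param feature_names length-p character.
#' @param grades length-n integer vector with values in 1..4.
#' @param sample_ids length-n character (defaults to `s1, s2, ...`).
#' @return an object of class `"feature_table"`.
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          grades, sample_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(feature_names) || length(feature_names) != p)
    stop_voxtex("feature_names must name every column",
                "voxtex_error_bad_table")
  if (length(grades) != n || !all(grades %in% 1:4))
    stop_voxtex("grades must be one label in 1..4 per row",
                "voxtex_error_bad_table")
  if (anyNA(values) || !all(is.finite(values)))
    stop_voxtex("feature values must be finite and non-missing",
                "voxtex_error_bad_table")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (n <= p)
    warning(sprintf("feature table has n = %d samples for p = %d features",
                    n, p), call. = FALSE)
  colnames(values) <- feature_names
  rownames(values) <- sample_ids
  structure(list(values = values, feature_names = feature_names,
                 grades = as.integer(grades), sample_ids = sample_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features; grades: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d x grade %s", table(x$grades),
                            names(table(x$grades))), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, grade = x$grades, x$values,
             row.names = NULL, check.names = FALSE)
}

# Restrict a feature table to a subset of feature columns.
subset_features <- function(table, subset) {
  missing <- setdiff(subset, table$feature_names)
  if (length(missing) > 0L)
    stop_voxtex(sprintf("unknown features: %s", paste(missing, collapse = ", ")),
                "voxtex_error_bad_subset")
  feature_table(table$values[, subset, drop = FALSE], subset,
                table$grades, table$sample_ids)
}

#' Write a feature table as CSV
#'
#' One row per sample with `sample_id` and `grade` columns followed by the
#' named features.
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path with `sample_id` and `grade` columns.
#' @return a [feature_table()].
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feats <- setdiff(names(df), c("sample_id", "grade"))
  feature_table(as.matrix(df[feats]), feats, df$grade, df$sample_id)
}
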