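#' Wilks' lambda of a feature subset
#'
#' Computes the within-class scatter `W = sum_i sum_j (x_ij - xbar_i)
#' (x_ij - xbar_i)'` and total scatter `T = B + W = sum_i sum_j (x_ij -
#' xbar)(x_ij - xbar)'` over classes i and samples j, and returns
#' `lambda = det(W) / det(T)`.  Lambda lies in (0, 1]; small values mean
#' the class means are well separated relative to the within-class spread.
#'
#' @param table a [feature_table()].
#' @param subset feature names to evaluate (default: all).
#' @return a `"wilks_result"`: list with `lambda`, `W`, `B`,
#'   `feature_subset`.
#' @export
wilks_lambda <- function(table, subset = table$feature_names) {
  stopifnot(inherits(table, "feature_table"))
  if (length(subset) == 0L)
    stop_voxtex("subset must be non-empty", "voxtex_error_bad_subset")
  X <- table$values[, subset, drop = FALSE]
  g <- table$grades
  classes <- sort(unique(g))
  if (length(classes) < 2L)
    stop_voxtex("need >= 2 distinct grades", "voxtex_error_bad_table")
  if (any(table(g) < 2L))
    stop_voxtex("every class needs >= 2 samples", "voxtex_error_bad_table")
  p <- ncol(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  grand <- colMeans(X)
  for (cl in classes) {
    Xi <- X[g == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    centred <- sweep(Xi, 2, mi)
    W <- W + crossprod(centred)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  Tm <- W + B
  # lambda = det(W)/det(T) is invariant under per-feature rescaling (both
  # determinants pick up the same squared scale factor), so evaluate it on
  # variance-scaled matrices for numerical stability across feature scales.
  s <- sqrt(diag(Tm))
  if (any(s == 0))
    stop_voxtex(sprintf("zero-variance feature(s) in subset: %s",
                        paste(subset[s == 0], collapse = ", ")),
                "voxtex_error_singular_scatter")
  Ws <- W / tcrossprod(s)
  Ts <- Tm / tcrossprod(s)
  detT <- det(Ts)
  if (!is.finite(detT) || detT <= 0 || rcond_sym(Ts) < 1e-12)
    stop_voxtex(sprintf("total scatter is singular on subset {%s}; features are collinear",
                        paste(subset, collapse = ", ")),
                "voxtex_error_singular_scatter")
  lambda <- min(1, max(0, det(Ws) / detT))
  structure(list(lambda = lambda, W = W, B = B,
                 feature_subset = subset),
            class = "wilks_result")
}

# Reciprocal condition number of a symmetric PSD matrix via its eigenvalues.
rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# Lambda value alone, with singular subsets reported as NA.
wilks_lambda_value <- function(table, subset) {
  tryCatch(wilks_lambda(table, subset)$lambda,
           voxtex_error_singular_scatter = function(e) NA_real_)
}

#' Partial-lambda F statistic for entering a feature
#'
#' With g classes, n samples and p features already in the model, the F
#' statistic to add `candidate` is
#' `F = ((n - g - p) / (g - 1)) * (lambda_current / lambda_with - 1)`,
#' referred to an F distribution on `(g - 1, n - g - p)` degrees of
#' freedom.  `lambda_current = 1` for an empty model; with two classes and
#' an empty model F equals the squared pooled-variance two-sample t
#' statistic.
#'
#' @param table a [feature_table()].
#' @param current feature names already selected (possibly empty).
#' @param candidate feature name to test, not in `current`.
#' @return list with `F`, `p_value`, `lambda_with` (lambda after adding).
#' @export
f_to_enter <- function(table, current, candidate) {
  stopifnot(inherits(table, "feature_table"))
  if (candidate %in% current)
    stop_voxtex("candidate is already in the model", "voxtex_error_bad_subset")
  g <- length(unique(table$grades))
  n <- nrow(table$values)
  p <- length(current)
  df2 <- n - g - p
  if (df2 <= 0)
    stop_voxtex(sprintf("no residual degrees of freedom (n = %d, g = %d, p = %d)",
                        n, g, p),
                "voxtex_error_no_df")
  lam0 <- if (p == 0L) 1 else wilks_lambda_value(table, current)
  lam1 <- wilks_lambda_value(table, c(current, candidate))
  if (is.na(lam0))
    stop_voxtex("current subset has singular within-class scatter",
                "voxtex_error_singular_scatter")
  if (is.na(lam1)) {
    # candidate is collinear with the current model: no discriminatory gain
    return(list(F = 0, p_value = 1, lambda_with = lam0))
  }
  Fv <- max(0, (df2 / (g - 1)) * (lam0 / lam1 - 1))
  list(F = Fv, p_value = stats::pf(Fv, g - 1, df2, lower.tail = FALSE),
       lambda_with = lam1)
}

# F statistic for removing `feature` from `current` (partial lambda with
# the feature deleted; df2 gains one relative to entry at the same size).
f_to_remove <- function(table, current, feature) {
  g <- length(unique(table$grades))
  n <- nrow(table$values)
  p <- length(current)
  df2 <- n - g - p + 1
  reduced <- setdiff(current, feature)
  lam_full <- wilks_lambda_value(table, current)
  lam_red <- if (length(reduced) == 0L) 1 else wilks_lambda_value(table, reduced)
  if (is.na(lam_full) || is.na(lam_red) || df2 <= 0)
    return(list(F = Inf, p_value = 0))
  Fv <- max(0, (df2 / (g - 1)) * (lam_red / lam_full - 1))
  list(F = Fv, p_value = stats::pf(Fv, g - 1, df2, lower.tail = FALSE))
}

#' Stepwise discriminant feature selection
#'
#' Alternates forward and backward moves driven by partial-lambda F tests:
#' at each step the unselected feature with the largest F-to-enter joins the
#' model if its p-value is at most `alpha_enter`; then the selected feature
#' with the weakest F-to-remove leaves if its p-value exceeds
#' `alpha_remove`.  Iteration stops when neither move applies or after
#' `max_steps` actions.  Unlike pure forward or backward selection, a
#' feature may re-enter after removal (and vice versa), so early decisions
#' are not locked in.  Ties in F are broken by feature-name order.
#'
#' @param table a [feature_table()].
#' @param alpha_enter significance level to enter (default 0.01).
#' @param alpha_remove significance level to stay (default 0.01; must be
#'   `>= alpha_enter`).
#' @param max_steps cap on enter/remove actions.
#' @return a `"stepwise_trace"`: list with `steps` (data.frame: `step`,
#'   `action`, `feature`, `F`, `p_value`, `lambda_after`) and `selected`
#'   (final feature names, possibly empty with a warning).
#' @export
stepwise_select <- function(table, alpha_enter = 0.01, alpha_remove = 0.01,
                            max_steps = 100L) {
  stopifnot(inherits(table, "feature_table"))
  if (!(alpha_enter > 0 && alpha_enter <= alpha_remove && alpha_remove <= 1))
    stop_voxtex("need 0 < alpha_enter <= alpha_remove <= 1",
                "voxtex_error_bad_alpha")
  selected <- character(0)
  steps <- list()
  n_actions <- 0L
  repeat {
    changed <- FALSE
    # forward move
    candidates <- setdiff(table$feature_names, selected)
    g <- length(unique(table$grades))
    can_enter <- length(candidates) > 0L &&
      nrow(table$values) - g - length(selected) > 0L
    if (can_enter) {
      cand_sorted <- sort(candidates)       # name order breaks F ties
      stats_list <- lapply(cand_sorted, function(f)
        f_to_enter(table, selected, f))
      Fs <- vapply(stats_list, `[[`, numeric(1), "F")
      best <- which.max(Fs)
      if (stats_list[[best]]$p_value <= alpha_enter) {
        feat <- cand_sorted[best]
        selected <- c(selected, feat)
        n_actions <- n_actions + 1L
        steps[[n_actions]] <- data.frame(
          step = n_actions, action = "enter", feature = feat,
          F = stats_list[[best]]$F, p_value = stats_list[[best]]$p_value,
          lambda_after = stats_list[[best]]$lambda_with)
        changed <- TRUE
        if (n_actions >= max_steps) break
      }
    }
    # backward move: drop the weakest selected feature if it has become
    # non-significant (never the one just entered — its removal p-value
    # equals its entry p-value, which passed alpha_enter <= alpha_remove)
    if (length(selected) > 1L) {
      rem <- lapply(selected, function(f) f_to_remove(table, selected, f))
      ps <- vapply(rem, `[[`, numeric(1), "p_value")
      worst <- order(-ps, selected)[1]
      if (ps[worst] > alpha_remove) {
        feat <- selected[worst]
        selected <- setdiff(selected, feat)
        n_actions <- n_actions + 1L
        lam <- if (length(selected) > 0L)
          wilks_lambda_value(table, selected) else 1
        steps[[n_actions]] <- data.frame(
          step = n_actions, action = "remove", feature = feat,
          F = rem[[worst]]$F, p_value = ps[worst], lambda_after = lam)
        changed <- TRUE
        if (n_actions >= max_steps) break
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0L)
    warning("stepwise selection found no feature meeting alpha_enter",
            call. = FALSE)
  trace <- if (length(steps) > 0L) do.call(rbind, steps) else
    data.frame(step = integer(0), action = character(0),
               feature = character(0), F = numeric(0), p_value = numeric(0),
               lambda_after = numeric(0))
  structure(list(steps = trace, selected = selected,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("stepwise_trace: %d action(s), selected {%s}\n",
              nrow(x$steps), paste(x$selected, collapse = ", ")))
  if (nrow(x$steps) > 0L) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Principal component analysis on the correlation matrix
#'
#' Columns are standardized to zero mean and unit variance, and the
#' correlation matrix is eigendecomposed.  Eigenvalues sum to the number of
#' features; `proportions` are eigenvalue / p and `cumulative` their running
#' sum, mirroring the usual eigenvalue table (eigenvalue, difference,
#' proportion, cumulative).
#'
#' @param table a [feature_table()].
#' @return a `"pca_result"`: `eigenvalues` (descending), `proportions`,
#'   `cumulative`, `loadings` (p x p orthonormal), `feature_means`,
#'   `feature_sds`, `feature_names`.
#' @export
pca_correlation <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (nrow(X) < 2L)
    stop_voxtex("PCA needs >= 2 samples", "voxtex_error_bad_table")
  mus <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop_voxtex(sprintf("zero-variance feature(s): %s",
                        paste(table$feature_names[zero], collapse = ", ")),
                "voxtex_error_zero_variance")
  Z <- scale(X, center = mus, scale = sds)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  p <- ncol(X)
  structure(list(eigenvalues = ev,
                 proportions = ev / p,
                 cumulative = cumsum(ev) / p,
                 loadings = e$vectors,
                 feature_means = mus, feature_sds = sds,
                 feature_names = table$feature_names),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues
  df <- data.frame(Eigenvalue = ev,
                   Difference = c(-diff(ev), NA),
                   Proportion = x$proportions,
                   Cumulative = x$cumulative)
  cat(sprintf("pca_result: %d components\n", length(ev)))
  print(df, row.names = TRUE, digits = 5)
  invisible(x)
}

#' Project samples onto retained principal components
#'
#' Standardizes with the training means/sds stored in the PCA result and
#' multiplies by the first k loadings.  The component count is either given
#' directly (`k`) or chosen as the smallest count whose cumulative
#' explained proportion reaches `cum_threshold`.
#'
#' @param table a [feature_table()] with the same features as the PCA.
#' @param pca a [pca_correlation()] result.
#' @param k number of components to keep.
#' @param cum_threshold cumulative-proportion target in (0, 1\]; ignored if
#'   `k` is given.
#' @return a [feature_table()] with columns `PC1..PCk`.
#' @export
project_components <- function(table, pca, k = NULL, cum_threshold = 0.95) {
  stopifnot(inherits(table, "feature_table"), inherits(pca, "pca_result"))
  p <- length(pca$eigenvalues)
  if (is.null(k)) {
    if (!(cum_threshold > 0 && cum_threshold <= 1))
      stop_voxtex("cum_threshold must lie in (0, 1]", "voxtex_error_bad_k")
    k <- which(pca$cumulative >= cum_threshold - 1e-12)[1]
    if (is.na(k)) k <- p
  }
  if (!is_count(k) || k < 1 || k > p)
    stop_voxtex(sprintf("k must lie in 1..%d", p), "voxtex_error_bad_k")
  if (!identical(table$feature_names, pca$feature_names))
    stop_voxtex("feature names do not match the PCA result",
                "voxtex_error_bad_subset")
  Z <- scale(table$values, center = pca$feature_means,
             scale = pca$feature_sds)
  scores <- Z %*% pca$loadings[, seq_len(k), drop = FALSE]
  suppressWarnings(
    feature_table(scores, paste0("PC", seq_len(k)), table$grades,
                  table$sample_ids))
}
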