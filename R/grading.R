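#' Linear discriminant analysis with pooled covariance
#'
#' Fits class means and the pooled within-class covariance, giving the
#' linear discriminant score
#' `d_c(x) = mu_c' S^-1 x - 0.5 mu_c' S^-1 mu_c + log pi_c`
#' for each class c.  Classification is by the largest score; ties go to
#' the lower grade label (deterministic, documented).
#'
#' @param table a [feature_table()] with >= 2 samples per class.
#' @param priors `"uniform"` (default; the study's grade counts are a
#'   sampling artefact, not population frequencies) or `"empirical"`
#'   (training class proportions).
#' @return an `"lda_model"`: `class_means` (g x k), `pooled_covariance`
#'   (k x k), `priors`, `classes`, `feature_names`.
#' @export
lda_fit <- function(table, priors = c("uniform", "empirical")) {
  stopifnot(inherits(table, "feature_table"))
  priors <- match.arg(priors)
  X <- table$values
  g <- table$grades
  classes <- sort(unique(g))
  counts <- table(factor(g, levels = classes))
  if (any(counts < 2L))
    stop_voxtex("every class needs >= 2 training samples",
                "voxtex_error_bad_table")
  k <- ncol(X)
  n <- nrow(X)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[g == cl, , drop = FALSE])))
  W <- matrix(0, k, k)
  for (cl in classes) {
    centred <- sweep(X[g == cl, , drop = FALSE], 2,
                     means[match(cl, classes), ])
    W <- W + crossprod(centred)
  }
  # ML divisor n (not n - g): classification is invariant to the scale of
  # S, and this makes the fit exactly invariant to duplicating the data
  S <- W / n
  ds <- sqrt(diag(as.matrix(S)))
  if (any(ds == 0) || rcond_sym(S / tcrossprod(ds)) < 1e-12)
    stop_voxtex(paste("pooled covariance is singular; reduce the feature set",
                      "(e.g. PCA or stepwise selection) before fitting"),
                "voxtex_error_singular_covariance")
  pi_c <- if (priors == "uniform") rep(1 / length(classes), length(classes))
          else as.numeric(counts) / n
  structure(list(class_means = means, pooled_covariance = S,
                 priors = pi_c, classes = classes,
                 feature_names = table$feature_names),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes (%s), %d feature(s)\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$class_means)))
  invisible(x)
}

#' Discriminant scores and grade prediction
#'
#' `lda_scores()` returns the n x g matrix of linear discriminant scores;
#' `lda_predict()` returns the argmax grade per sample, breaking exact ties
#' toward the lower grade.
#'
#' @param model an [lda_fit()] model.
#' @param table a [feature_table()] whose features match the model.
#' @return `lda_predict()`: integer grades; `lda_scores()`: numeric matrix.
#' @export
lda_scores <- function(model, table) {
  stopifnot(inherits(model, "lda_model"), inherits(table, "feature_table"))
  if (!identical(table$feature_names, model$feature_names))
    stop_voxtex("feature names/order do not match the model",
                "voxtex_error_feature_mismatch")
  X <- table$values
  # invert in correlation space for stability across feature scales
  ds <- sqrt(diag(as.matrix(model$pooled_covariance)))
  Dinv <- diag(1 / ds, nrow = length(ds))
  Sinv <- Dinv %*% solve(model$pooled_covariance / tcrossprod(ds)) %*% Dinv
  A <- model$class_means %*% Sinv                 # g x k
  const <- -0.5 * rowSums(A * model$class_means) + log(model$priors)
  scores <- X %*% t(A)
  sweep(scores, 2, const, `+`)
}

#' @rdname lda_scores
#' @export
lda_predict <- function(model, table) {
  s <- lda_scores(model, table)
  # which.max takes the first maximum; classes are sorted ascending, so
  # exact ties resolve to the lower grade
  model$classes[apply(s, 1, which.max)]
}

#' Confusion matrix and accuracy report
#'
#' @param true,predicted integer grade labels in 1..4, equal length.
#' @return a `"confusion_report"`: `matrix` (4 x 4, true grade in rows),
#'   `per_grade_accuracy` (diagonal over row sums; `NaN` for grades absent
#'   from `true`), `overall_accuracy` (trace over total), `n`.
#' @export
evaluate <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop_voxtex("label vectors differ in length", "voxtex_error_length_mismatch")
  if (!all(true %in% 1:4) || !all(predicted %in% 1:4))
    stop_voxtex("labels must lie in 1..4", "voxtex_error_bad_labels")
  m <- table(factor(true, levels = 1:4), factor(predicted, levels = 1:4))
  m <- unclass(m)
  dimnames(m) <- list(true = 1:4, predicted = 1:4)
  rs <- rowSums(m)
  structure(list(matrix = m,
                 per_grade_accuracy = diag(m) / rs,
                 overall_accuracy = sum(diag(m)) / sum(m),
                 n = length(true)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion_report: overall accuracy %.2f%% (n = %d)\n",
              100 * x$overall_accuracy, x$n))
  print(x$matrix)
  pg <- x$per_grade_accuracy
  cat("per-grade accuracy:",
      paste(sprintf("G%d %.1f%%", 1:4, 100 * pg), collapse = ", "), "\n")
  invisible(x)
}

#' The six classifier configurations
#'
#' Each configuration pairs one texture family with one selection method:
#' \tabular{llll}{
#'   id \tab texture \tab selection \tab raw features \cr
#'   A \tab wavelet-haar \tab stepwise \tab 16 \cr
#'   B \tab wavelet-haar \tab pca \tab 16 \cr
#'   C \tab wavelet-db2 \tab stepwise \tab 16 \cr
#'   D \tab wavelet-db2 \tab pca \tab 16 \cr
#'   E \tab glcm \tab stepwise \tab 12 \cr
#'   F \tab glcm \tab pca \tab 12 \cr
#' }
#'
#' @param id one of `"A"`..`"F"`.
#' @return a `"classifier_config"`: `id`, `texture`, `selection`,
#'   `n_raw_features`.
#' @export
classifier_config <- function(id) {
  spec <- list(A = c("wavelet-haar", "stepwise"),
               B = c("wavelet-haar", "pca"),
               C = c("wavelet-db2", "stepwise"),
               D = c("wavelet-db2", "pca"),
               E = c("glcm", "stepwise"),
               F = c("glcm", "pca"))
  if (!is.character(id) || length(id) != 1L || !id %in% names(spec))
    stop_voxtex("config id must be one of A..F", "voxtex_error_bad_config")
  s <- spec[[id]]
  structure(list(id = id, texture = s[1], selection = s[2],
                 n_raw_features = if (s[1] == "glcm") 12L else 16L),
            class = "classifier_config")
}

#' Run one classifier configuration end to end
#'
#' Applies the configuration's feature selection fitted on the training
#' table only (no test-set leakage), fits the LDA on the reduced training
#' table, predicts the identically transformed test table, and reports a
#' confusion matrix.  For PCA configurations the retained component count
#' defaults to 8 for the 16 wavelet features and 5 for the 12 co-occurrence
#' features (`pca_k = NULL` switches to the cumulative-proportion rule at
#' `pca_cumulative`).
#'
#' @param config a [classifier_config()] (or its id letter).
#' @param train,test [feature_table()]s carrying the configuration's raw
#'   feature schema.
#' @param alpha_enter,alpha_remove stepwise significance levels.
#' @param pca_k fixed component count (default 8 wavelet / 5 co-occurrence).
#' @param pca_cumulative cumulative threshold used when `pca_k` is `NULL`.
#' @param priors passed to [lda_fit()].
#' @return list with `config`, `model`, `report` (a `"confusion_report"`),
#'   `selection` (the `"stepwise_trace"` or `"pca_result"`), `selected`
#'   (feature or component names used), `train_report`.
#' @export
run_config <- function(config, train, test,
                       alpha_enter = 0.01, alpha_remove = 0.01,
                       pca_k = "default", pca_cumulative = 0.95,
                       priors = "uniform") {
  if (is.character(config)) config <- classifier_config(config)
  stopifnot(inherits(config, "classifier_config"),
            inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!identical(train$feature_names, test$feature_names))
    stop_voxtex("train and test tables must share one feature schema",
                "voxtex_error_feature_mismatch")
  if (config$selection == "stepwise") {
    sel <- stepwise_select(train, alpha_enter, alpha_remove)
    if (length(sel$selected) == 0L)
      return(list(config = config, model = NULL, report = NULL,
                  selection = sel, selected = character(0),
                  failure = "stepwise selection retained no feature"))
    tr <- subset_features(train, sel$selected)
    te <- subset_features(test, sel$selected)
    used <- sel$selected
  } else {
    sel <- pca_correlation(train)
    k <- if (identical(pca_k, "default")) {
      if (config$texture == "glcm") 5L else 8L
    } else pca_k
    tr <- project_components(train, sel, k = k,
                             cum_threshold = pca_cumulative)
    te <- project_components(test, sel, k = ncol(tr$values),
                             cum_threshold = pca_cumulative)
    used <- tr$feature_names
  }
  model <- lda_fit(tr, priors = priors)
  list(config = config,
       model = model,
       report = evaluate(test$grades, lda_predict(model, te)),
       selection = sel,
       selected = used,
       train_report = evaluate(train$grades, lda_predict(model, tr)))
}

#' Run all six configurations and tabulate accuracies
#'
#' @param tables named list with elements `"wavelet-haar"`, `"wavelet-db2"`,
#'   `"glcm"`, each a `list(train = , test = )` of [feature_table()]s.
#' @param ... passed to [run_config()].
#' @return list with `runs` (per-config results, names A..F) and `summary`
#'   (data.frame: config, texture, selection, n_features_used, per-grade and
#'   overall test accuracy in percent).
#' @export
run_all_configs <- function(tables, ...) {
  ids <- c("A", "B", "C", "D", "E", "F")
  runs <- lapply(ids, function(id) {
    cfg <- classifier_config(id)
    fam <- tables[[cfg$texture]]
    if (is.null(fam))
      stop_voxtex(sprintf("tables lacks an element '%s'", cfg$texture),
                  "voxtex_error_bad_config")
    run_config(cfg, fam$train, fam$test, ...)
  })
  names(runs) <- ids
  summary <- do.call(rbind, lapply(runs, function(r) {
    acc <- if (is.null(r$report)) rep(NA_real_, 5) else
      c(r$report$per_grade_accuracy, r$report$overall_accuracy)
    data.frame(config = r$config$id, texture = r$config$texture,
               selection = r$config$selection,
               n_features_used = length(r$selected),
               grade1 = 100 * acc[1], grade2 = 100 * acc[2],
               grade3 = 100 * acc[3], grade4 = 100 * acc[4],
               overall = 100 * acc[5])
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
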