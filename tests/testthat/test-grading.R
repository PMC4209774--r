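test_that("lda_fit: 1-D boundary, sufficiency, and the algebra oracle", {
  set.seed(601)
  x <- c(rnorm(60, 0), rnorm(60, 10))
  ft <- suppressWarnings(feature_table(matrix(x), "x",
                                       rep(1:2, each = 60)))
  m <- lda_fit(ft)
  # equal priors, shared variance: boundary where the two scores cross
  s <- lda_scores(m, suppressWarnings(
    feature_table(matrix(seq(0, 10, 0.01)), "x",
                  rep(1, 1001))))
  boundary <- seq(0, 10, 0.01)[which.min(abs(s[, 1] - s[, 2]))]
  expect_equal(boundary, 5, tolerance = 0.6)
  # duplicating the training data leaves the model unchanged
  ft2 <- suppressWarnings(feature_table(rbind(ft$values, ft$values), "x",
                                        rep(ft$grades, 2)))
  m2 <- lda_fit(ft2)
  expect_equal(m$class_means, m2$class_means)
  expect_equal(m$pooled_covariance, m2$pooled_covariance)
  # k = 2, g = 3: scores match the explicit formula per sample
  tab <- toy_grade_table(n_per = 8, p = 2, sep = 2, seed = 602)
  tab$grades[tab$grades == 4] <- 3
  tab <- suppressWarnings(feature_table(tab$values, tab$feature_names,
                                        tab$grades))
  m3 <- lda_fit(tab)
  sc <- lda_scores(m3, tab)
  Sinv <- solve(m3$pooled_covariance)
  for (r in c(1, 9, 20)) {
    x_r <- tab$values[r, ]
    for (ci in seq_along(m3$classes)) {
      mu <- m3$class_means[ci, ]
      d <- sum(mu * (Sinv %*% x_r)) - 0.5 * sum(mu * (Sinv %*% mu)) +
        log(m3$priors[ci])
      expect_equal(unname(sc[r, ci]), unname(d), tolerance = 1e-10)
    }
  }
  # singular pooled covariance refuses to fit
  dup <- suppressWarnings(feature_table(
    cbind(tab$values, c2 = tab$values[, 1]),
    c(tab$feature_names, "c2"), tab$grades))
  expect_error(lda_fit(dup), class = "voxtex_error_singular_covariance")
})

test_that("lda agrees with MASS::lda on a toy problem", {
  skip_if_not_installed("MASS")
  tab <- toy_grade_table(n_per = 12, p = 3, sep = 1.5, seed = 603)
  m <- lda_fit(tab)
  ours <- lda_predict(m, tab)
  ref <- MASS::lda(tab$values, grouping = tab$grades,
                   prior = rep(0.25, 4))
  theirs <- as.integer(as.character(stats::predict(ref, tab$values)$class))
  expect_equal(ours, theirs)
})

test_that("lda_predict: class means, tie-breaking, statelessness", {
  tab <- toy_grade_table(n_per = 8, p = 2, sep = 3, seed = 604)
  m <- lda_fit(tab)
  means_tab <- suppressWarnings(feature_table(m$class_means,
                                              tab$feature_names, 1:4))
  expect_equal(lda_predict(m, means_tab), 1:4)
  # exact tie between two classes with shared isotropic covariance:
  # midpoint scores are equal, the lower grade wins
  Xt <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
              matrix(rnorm(40, 6, 1), 20, 2))
  # force exactly symmetric means and covariance by construction
  mt <- structure(list(class_means = rbind(c(0, 0), c(6, 6)),
                       pooled_covariance = diag(2), priors = c(0.5, 0.5),
                       classes = c(2L, 3L), feature_names = c("a", "b")),
                  class = "lda_model")
  mid <- suppressWarnings(feature_table(matrix(c(3, 3), 1), c("a", "b"), 1))
  expect_equal(lda_predict(mt, mid), 2L)
  # batch equals one-at-a-time
  batch <- lda_predict(m, tab)
  singles <- vapply(seq_len(nrow(tab$values)), function(r)
    lda_predict(m, suppressWarnings(feature_table(
      tab$values[r, , drop = FALSE], tab$feature_names, tab$grades[r]))),
    integer(1))
  expect_equal(batch, singles)
  wrong <- suppressWarnings(feature_table(tab$values,
                                          paste0("g", 1:2), tab$grades))
  expect_error(lda_predict(m, wrong),
               class = "voxtex_error_feature_mismatch")
})

test_that("evaluate: identity, constant predictor, and the hand count", {
  r1 <- evaluate(rep(1:4, each = 3), rep(1:4, each = 3))
  expect_equal(r1$overall_accuracy, 1)
  expect_equal(unname(diag(r1$matrix)), rep(3L, 4), ignore_attr = TRUE)
  r2 <- evaluate(rep(1:4, each = 5), rep(2, 20))
  expect_equal(r2$overall_accuracy, 0.25)
  r3 <- evaluate(c(1, 1, 2, 2, 3, 3, 4, 4), c(1, 2, 2, 2, 3, 3, 4, 1))
  expect_equal(r3$overall_accuracy, 0.75)
  expect_equal(unname(r3$per_grade_accuracy), c(0.5, 1, 1, 0.5))
  expect_error(evaluate(1:4, 1:5), class = "voxtex_error_length_mismatch")
  expect_error(evaluate(c(1, 5), c(1, 1)), class = "voxtex_error_bad_labels")
})

test_that("overall accuracy is the count-weighted mean of per-grade accuracies", {
  set.seed(605)
  for (rep in 1:20) {
    true <- sample(1:4, 40, replace = TRUE)
    pred <- sample(1:4, 40, replace = TRUE)
    r <- evaluate(true, pred)
    counts <- rowSums(r$matrix)
    pg <- r$per_grade_accuracy
    keep <- counts > 0
    expect_equal(r$overall_accuracy,
                 sum(pg[keep] * counts[keep]) / sum(counts))
  }
})

test_that("classifier_config mirrors the six-configuration design", {
  expected <- list(A = c("wavelet-haar", "stepwise", 16L),
                   B = c("wavelet-haar", "pca", 16L),
                   C = c("wavelet-db2", "stepwise", 16L),
                   D = c("wavelet-db2", "pca", 16L),
                   E = c("glcm", "stepwise", 12L),
                   F = c("glcm", "pca", 12L))
  for (id in names(expected)) {
    cfg <- classifier_config(id)
    expect_equal(cfg$texture, expected[[id]][1])
    expect_equal(cfg$selection, expected[[id]][2])
    expect_equal(cfg$n_raw_features, as.integer(expected[[id]][3]))
  }
  expect_error(classifier_config("G"), class = "voxtex_error_bad_config")
})

test_that("run_config: perfect separation, no leakage, PCA path", {
  # well-separated Gaussian classes -> 100% test accuracy
  train <- toy_grade_table(n_per = 10, p = 6, sep = 6, seed = 606)
  test <- toy_grade_table(n_per = 6, p = 6, sep = 6, seed = 607)
  cfgE <- classifier_config("E")   # stepwise path (schema-agnostic here)
  r <- run_config(cfgE, train, test)
  expect_equal(r$report$overall_accuracy, 1)
  expect_s3_class(r$selection, "stepwise_trace")
  # selection is fitted on training data only: shuffling test rows changes
  # nothing about the selected features or the model
  perm <- sample(nrow(test$values))
  test_perm <- suppressWarnings(feature_table(test$values[perm, ],
                                              test$feature_names,
                                              test$grades[perm]))
  r2 <- run_config(cfgE, train, test_perm)
  expect_equal(r$selected, r2$selected)
  expect_equal(r$model$class_means, r2$model$class_means)
  expect_equal(r$report$overall_accuracy, r2$report$overall_accuracy)
  # PCA configuration retains the requested component count
  rB <- run_config(classifier_config("F"), train, test, pca_k = 3)
  expect_equal(rB$selected, c("PC1", "PC2", "PC3"))
  expect_s3_class(rB$selection, "pca_result")
  expect_gt(rB$report$overall_accuracy, 0.9)
  # mismatched schemas refuse to run
  bad <- suppressWarnings(feature_table(test$values,
                                        paste0("x", 1:6), test$grades))
  expect_error(run_config(cfgE, train, bad),
               class = "voxtex_error_feature_mismatch")
})

test_that("harder problems never look easier: accuracy monotone in separation", {
  mean_acc <- function(sep) {
    accs <- vapply(1:20, function(s) {
      tr <- toy_grade_table(n_per = 8, p = 4, sep = sep, seed = 700 + s)
      te <- toy_grade_table(n_per = 5, p = 4, sep = sep, seed = 800 + s)
      run_config(classifier_config("F"), tr, te,
                 pca_k = 3)$report$overall_accuracy
    }, numeric(1))
    mean(accs)
  }
  expect_gte(mean_acc(3), mean_acc(0.8))
  expect_gte(mean_acc(0.8), mean_acc(0.2))
})
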