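test_that("wilks_lambda matches the double-loop oracle and its limits", {
  set.seed(301)
  X <- matrix(rnorm(24), 12, 2)
  g <- rep(1:3, each = 4)
  X[, 1] <- X[, 1] + 2 * g
  ft <- suppressWarnings(feature_table(X, c("a", "b"), g))
  w <- wilks_lambda(ft)
  expect_equal(w$lambda, oracle_wilks(X, g), tolerance = 1e-12)
  expect_true(w$lambda > 0 && w$lambda <= 1)
  expect_equal(w$W, t(w$W))
  expect_true(all(eigen(w$B, symmetric = TRUE)$values > -1e-9))
  # B = 0 exactly when every class holds identical rows -> lambda = 1
  rows <- matrix(rnorm(8), 4, 2)
  Xe <- rbind(rows, rows, rows)
  fte <- suppressWarnings(feature_table(Xe, c("a", "b"), rep(1:3, each = 4)))
  expect_equal(wilks_lambda(fte)$lambda, 1, tolerance = 1e-12)
  # permuting labels of one pooled sample: lambda near 1
  set.seed(302)
  Xp <- matrix(rnorm(400), 200, 2)
  ftp <- feature_table(Xp, c("a", "b"), sample(rep(1:4, each = 50)))
  expect_gt(wilks_lambda(ftp)$lambda, 0.9)
  # separation -> infinity drives lambda -> 0
  Xs <- matrix(rnorm(40), 20, 2)
  Xs[, 1] <- Xs[, 1] + 1000 * rep(1:2, each = 10)
  fts <- suppressWarnings(feature_table(Xs, c("a", "b"),
                                        rep(1:2, each = 10)))
  expect_lt(wilks_lambda(fts)$lambda, 1e-4)
  # collinear subset raises a named error
  Xc <- cbind(Xs[, 1], Xs[, 1])
  ftc <- suppressWarnings(feature_table(Xc, c("a", "a2"),
                                        rep(1:2, each = 10)))
  expect_error(wilks_lambda(ftc), class = "voxtex_error_singular_scatter")
  expect_error(wilks_lambda(ft, character(0)),
               class = "voxtex_error_bad_subset")
})

test_that("wilks_lambda is invariant to feature scale", {
  set.seed(303)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(1:4, each = 5)
  X[, 2] <- X[, 2] + g
  ft1 <- suppressWarnings(feature_table(X, c("a", "b", "c"), g))
  X2 <- sweep(X, 2, c(1e8, 1e-6, 1), `*`)
  ft2 <- suppressWarnings(feature_table(X2, c("a", "b", "c"), g))
  expect_equal(wilks_lambda(ft1)$lambda, wilks_lambda(ft2)$lambda,
               tolerance = 1e-9)
})

test_that("f_to_enter: duplicates, t-squared equivalence, perfect separation", {
  tab <- toy_grade_table(n_per = 8, p = 4, sep = 2, seed = 304)
  # duplicate of an entered feature gains nothing
  dup <- suppressWarnings(feature_table(
    cbind(tab$values, f1b = tab$values[, "f1"]),
    c(tab$feature_names, "f1b"), tab$grades))
  r <- f_to_enter(dup, "f1", "f1b")
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
  # two classes, empty model: F equals the pooled two-sample t^2
  set.seed(305)
  x <- c(rnorm(9), rnorm(12, 1.5))
  g <- rep(1:2, c(9, 12))
  ft2 <- suppressWarnings(feature_table(matrix(x), "x", g))
  tt <- stats::t.test(x[g == 1], x[g == 2], var.equal = TRUE)
  expect_equal(f_to_enter(ft2, character(0), "x")$F,
               unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(f_to_enter(ft2, character(0), "x")$p_value,
               tt$p.value, tolerance = 1e-9)
  # perfectly separating candidate: p below any fixed alpha
  xp <- rep(c(0, 10), each = 6) + rep(c(0, 1e-6, -1e-6), 4)
  ftp <- suppressWarnings(feature_table(matrix(xp), "x",
                                        rep(1:2, each = 6)))
  expect_lt(f_to_enter(ftp, character(0), "x")$p_value, 1e-12)
  expect_error(f_to_enter(ft2, "x", "x"), class = "voxtex_error_bad_subset")
})

test_that("stepwise selection: signal first, monotone lambda, guards", {
  # one strong discriminative feature among pure noise enters first
  set.seed(306)
  X <- matrix(rnorm(40 * 10), 40, 10)
  g <- rep(1:4, each = 10)
  X[, 7] <- X[, 7] + 3 * g
  ft <- feature_table(X, paste0("f", 1:10), g)
  tr <- stepwise_select(ft)
  expect_equal(tr$steps$feature[1], "f7")
  expect_equal(tr$steps$action[1], "enter")
  # alpha = 1: everything enters, lambda non-increasing, nothing removed
  small <- toy_grade_table(n_per = 10, p = 5, sep = 2, seed = 307)
  tr2 <- stepwise_select(small, alpha_enter = 1, alpha_remove = 1,
                         max_steps = 5)
  expect_setequal(tr2$selected, small$feature_names)
  expect_true(all(tr2$steps$action == "enter"))
  expect_true(all(diff(tr2$steps$lambda_after) <= 1e-12))
  # at the default significance levels a duplicate of an entered feature
  # is never entered (F-to-enter 0, p-value 1; W-singularity guarded)
  dup <- suppressWarnings(feature_table(
    cbind(small$values, f1b = small$values[, "f1"]),
    c(small$feature_names, "f1b"), small$grades))
  tr3 <- stepwise_select(dup)
  expect_true("f1" %in% tr3$selected)
  expect_false("f1b" %in% tr3$selected)
  # no candidate meeting alpha: empty selection with a warning, not an error
  set.seed(308)
  noise <- feature_table(matrix(rnorm(120), 40, 3), paste0("n", 1:3),
                         rep(1:4, each = 10))
  expect_warning(tr4 <- stepwise_select(noise, alpha_enter = 1e-6,
                                        alpha_remove = 1e-6),
                 "no feature")
  expect_length(tr4$selected, 0)
  expect_error(stepwise_select(small, alpha_enter = 0.5, alpha_remove = 0.1),
               class = "voxtex_error_bad_alpha")
})

test_that("stepwise never oscillates with equal alphas (100 random tables)", {
  for (s in 1:100) {
    tab <- toy_grade_table(n_per = 6, p = 4, sep = runif(1, 0, 2),
                           n_signal = sample(0:3, 1), seed = 400 + s)
    tr <- suppressWarnings(
      stepwise_select(tab, alpha_enter = 0.05, alpha_remove = 0.05,
                      max_steps = 20))
    st <- tr$steps
    if (nrow(st) >= 2) {
      same_feat <- st$feature[-1] == st$feature[-nrow(st)]
      enter_then_remove <- st$action[-nrow(st)] == "enter" &
        st$action[-1] == "remove"
      expect_false(any(same_feat & enter_then_remove),
                   info = paste("seed", 400 + s))
    }
    expect_lt(nrow(st), 20)   # terminated before the cap
  }
})

test_that("correlation PCA: spectrum structure and invariants", {
  set.seed(309)
  big <- feature_table(matrix(rnorm(5000), 1000, 5), paste0("f", 1:5),
                       sample(1:4, 1000, replace = TRUE))
  p1 <- pca_correlation(big)
  expect_true(all(abs(p1$eigenvalues - 1) < 0.2))
  expect_true(all(abs(p1$proportions - 0.2) < 0.05))
  # two perfectly correlated features
  x <- rnorm(30)
  ft2 <- suppressWarnings(feature_table(cbind(a = x, b = 2 * x + 1),
                                        c("a", "b"),
                                        rep(1:2, 15)))
  p2 <- pca_correlation(ft2)
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p2$cumulative, c(1, 1), tolerance = 1e-12)
  # eigenvalue sum = p and final cumulative = 1 on arbitrary tables
  for (s in 1:5) {
    tab <- toy_grade_table(n_per = 6, p = 7, sep = 1, seed = 500 + s)
    pc <- pca_correlation(tab)
    expect_equal(sum(pc$eigenvalues), 7, tolerance = 1e-8)
    expect_equal(pc$cumulative[7], 1, tolerance = 1e-9)
    expect_equal(crossprod(pc$loadings), diag(7), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  }
  cz <- suppressWarnings(feature_table(cbind(a = rnorm(10), b = rep(3, 10)),
                                       c("a", "b"), rep(1:2, 5)))
  expect_error(pca_correlation(cz), class = "voxtex_error_zero_variance")
  expect_error(pca_correlation(cz), "b")
})

test_that("component projection: variance, thresholding, held-out samples", {
  tab <- toy_grade_table(n_per = 10, p = 6, sep = 2, seed = 310)
  pc <- pca_correlation(tab)
  full <- project_components(tab, pc, k = 6)
  expect_equal(sum(apply(full$values, 2, stats::var)), 6, tolerance = 1e-8)
  # threshold rule picks the first k whose cumulative reaches the target
  k95 <- ncol(project_components(tab, pc, cum_threshold = 0.95)$values)
  expect_equal(k95, which(pc$cumulative >= 0.95)[1])
  # the published 16-feature eigenvalue table: cumulative first reaches
  # 0.95 at component 8 (0.9559)
  cum16 <- c(0.7039, 0.7795, 0.8282, 0.8685, 0.8988, 0.9234, 0.9428,
             0.9559, 0.9666, 0.9763, 0.9836, 0.9892, 0.9939, 0.9978,
             0.9994, 1.0000)
  expect_equal(which(cum16 >= 0.95)[1], 8)
  # projecting one held-out sample equals its row in the batch projection
  batch <- project_components(tab, pc, k = 3)
  one <- suppressWarnings(feature_table(tab$values[5, , drop = FALSE],
                                        tab$feature_names,
                                        tab$grades[5]))
  alone <- project_components(one, pc, k = 3)
  expect_equal(unname(alone$values), unname(batch$values[5, , drop = FALSE]))
  expect_error(project_components(tab, pc, k = 9),
               class = "voxtex_error_bad_k")
})
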