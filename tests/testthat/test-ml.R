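test_that("oos R2 uses the test-fold mean and admits negative values", {
  expect_equal(oos_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(oos_r2(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(oos_r2(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_true(is.na(oos_r2(c(2, 2), c(1, 3))))
})

test_that("median-expression filter follows the midpoint-median convention", {
  X <- cbind(a = rep(1, 4), b = c(-1, -1, 1, 1), c = c(-2, -0.5, 1, 2))
  # b: median = 0 -> dropped; c: median = 0.25 > 0 -> kept
  expect_equal(select_median_expressed(X), c(1, 3))
  expect_equal(select_median_expressed(X[, 1, drop = FALSE]), 1)
  expect_error(select_median_expressed(-X[, 1, drop = FALSE]),
               "no features")
})

test_that("spearman filter selects a monotone signal and uses average ranks", {
  set.seed(30)
  n <- 56
  X <- matrix(rnorm(n * 30), n, 30)
  y <- exp(X[, 7])          # noiseless monotone function of feature 7
  sel <- select_spearman(X, y)
  expect_true(7 %in% sel)
  # ties handled by average ranks: duplicate-valued feature still scored
  X[, 8] <- round(X[, 7], 1)
  sel2 <- select_spearman(X, y)
  expect_true(all(c(7, 8) %in% sel2))
  # pure noise with tiny n: deterministic given data (either empty-error
  # or a fixed small set)
  set.seed(31)
  Xn <- matrix(rnorm(20 * 10), 20, 10)
  yn <- rnorm(20)
  r1 <- tryCatch(select_spearman(Xn, yn), error = function(e) "none")
  r2 <- tryCatch(select_spearman(Xn, yn), error = function(e) "none")
  expect_identical(r1, r2)
})

test_that("HSIC scores equal the brute-force trace oracle on toy data", {
  set.seed(32)
  x <- rnorm(6); y <- rnorm(6)
  gram <- function(v) {
    n <- length(v)
    K <- exp(-outer(v, v, `-`)^2 / (2 * sd(v)^2))
    H <- diag(n) - matrix(1 / n, n, n)
    Kc <- H %*% K %*% H
    Kc / sqrt(sum(Kc * Kc))
  }
  brute <- sum(diag(gram(x) %*% gram(y))) / (6 - 1)^2
  expect_equal(hsic_score(x, y), brute, tolerance = 1e-12)
})

test_that("HSIC lasso finds nonlinear signal and caps its selection", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 40), n, 40)
  y <- X[, 5]^2 + rnorm(n, 0, 0.1)   # invisible to linear correlation
  sel <- hsic_lasso_select(X, y)
  expect_equal(sel[1], 5)
  expect_lte(length(sel), 200)
  # prefilter keeps the most variable candidates
  X2 <- X
  X2[, 12] <- X2[, 12] * 10
  sel2 <- hsic_lasso_select(X2, y, prefilter = 1)
  expect_true(all(sel2 %in% 12))
  # constant features are excluded before solving
  X3 <- cbind(X, const = 1)
  expect_false(41 %in% hsic_lasso_select(X3, y))
})

test_that("elastic net recovers sparse linear signal and groups duplicates", {
  set.seed(34)
  n <- 56; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- 1.5 * X[, 1] - 2 * X[, 2] + X[, 3]
  te <- 45:56; tr <- 1:44
  f <- fit_predict_enet(X[tr, ], y[tr], X[te, ], seed = 1)
  expect_gte(oos_r2(y[te], f$predictions), 0.95)
  top <- order(abs(f$coefficients), decreasing = TRUE)[1:3]
  expect_setequal(top, 1:3)
  # duplicated columns: predictions are unchanged and the coefficient mass
  # on the duplicate pair matches the single-column fit; at any mixing
  # below pure lasso the weight is shared across the pair
  yd <- 2 * X[, 1] + rnorm(n, 0, 0.1)
  X1 <- X[, 1:20]
  Xd <- cbind(X[, 1], X1)
  f1 <- fit_predict_enet(X1[tr, ], yd[tr], X1[te, ], seed = 1)
  fd <- fit_predict_enet(Xd[tr, ], yd[tr], Xd[te, ], seed = 1)
  expect_equal(oos_r2(yd[te], fd$predictions),
               oos_r2(yd[te], f1$predictions), tolerance = 0.02)
  expect_equal(unname(fd$coefficients[1] + fd$coefficients[2]),
               unname(f1$coefficients[1]), tolerance = 0.1)
  if (fd$alpha < 1)
    expect_equal(unname(fd$coefficients[1]), unname(fd$coefficients[2]),
                 tolerance = 0.05)
  # pure-noise outcome: near-intercept-only model
  set.seed(35)
  yn <- rnorm(n)
  fn <- fit_predict_enet(X[tr, ], yn[tr], X[te, ], seed = 1)
  expect_lt(sd(fn$predictions), sd(yn))
})

test_that("random forest honours its oob grid search and is reproducible", {
  set.seed(36)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  y <- ifelse(X[, 4] > 0, 3, -3) + rnorm(n, 0, 0.2)
  te <- 49:60; tr <- 1:48
  f <- fit_predict_rf(X[tr, ], y[tr], X[te, ], seed = 2, num_trees = 300)
  expect_gt(f$importances[4] / sum(f$importances), 0.5)
  expect_equal(f$oob_error, min(f$oob_grid$oob))
  f2 <- fit_predict_rf(X[tr, ], y[tr], X[te, ], seed = 2, num_trees = 300)
  expect_identical(f$predictions, f2$predictions)
  expect_gt(oos_r2(y[te], f$predictions), 0.5)
})

test_that("repeated CV is deterministic and obeys the median conventions", {
  set.seed(37)
  n <- 50; p <- 30
  X <- matrix(rnorm(n * p), n, p) + 1   # positive median -> median filter
  y <- 2 * X[, 1] + rnorm(n, 0, 0.5)
  r1 <- run_repeated_cv(X, y, "median", "enet", n_repeats = 2,
                        n_folds = 5, seed = 7)
  r2 <- run_repeated_cv(X, y, "median", "enet", n_repeats = 2,
                        n_folds = 5, seed = 7)
  expect_identical(r1$split_r2, r2$split_r2)
  expect_identical(r1$median_test_r2, r2$median_test_r2)
  # median of an even split count is the midpoint of the two central
  # order statistics
  expect_false(anyNA(r1$split_r2))
  s <- sort(r1$split_r2)
  k <- length(s) / 2
  expect_equal(r1$median_test_r2, (s[k] + s[k + 1]) / 2)
  expect_gt(r1$median_test_r2, 0.5)
  # fold partition: every sample in exactly one test fold per repeat
  f <- make_cv_folds(50, 10, 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(as.integer(table(f)), rep(5L, 10))
})

test_that("pooled PCC is computed on concatenated predictions, not per fold", {
  # constructed counterexample where the mean of per-fold correlations
  # differs from the pooled correlation
  y <- c(1, 2, 101, 102)
  pred <- c(2, 1, 102, 101)     # per-fold (pairs) correlation = -1
  folds <- c(1, 1, 2, 2)
  pooled <- cor(y, pred)
  per_fold <- mean(c(cor(y[1:2], pred[1:2]), cor(y[3:4], pred[3:4])))
  expect_gt(pooled, 0.99)
  expect_equal(per_fold, -1)
  # the result object stores one pooled value per repeat
  set.seed(38)
  X <- matrix(rnorm(40 * 10), 40, 10) + 1
  yy <- X[, 1] + rnorm(40, 0, 0.3)
  r <- run_repeated_cv(X, yy, "median", "enet", n_repeats = 2,
                       n_folds = 4, seed = 1)
  expect_length(r$pooled_pcc, 2)
  expect_length(r$split_r2, 8)
})

test_that("permutation baseline percentile uses linear interpolation", {
  set.seed(39)
  X <- matrix(rnorm(40 * 15), 40, 15) + 1
  y <- rnorm(40)
  pb <- permutation_baseline(X, y, "median", "enet", n_perm = 20, seed = 3)
  expect_length(pb$r2_perm, 20)
  expect_equal(pb$percentile_95,
               unname(quantile(pb$r2_perm, 0.95, type = 7, na.rm = TRUE)))
})

test_that("importance ranking restricts to the best selector", {
  set.seed(40)
  X <- matrix(rnorm(45 * 12), 45, 12) + 1
  colnames(X) <- paste0("g", 1:12)
  y <- 3 * X[, 2] + rnorm(45, 0, 0.4)
  res <- list(
    median = run_repeated_cv(X, y, "median", "enet", n_repeats = 2,
                             n_folds = 5, seed = 2),
    spearman = run_repeated_cv(X, y, "spearman", "enet", n_repeats = 2,
                               n_folds = 5, seed = 2))
  tab <- rank_feature_importance(res, top_k = 5)
  expect_equal(tab$feature[1], "g2")
  best <- attr(tab, "best_selector")
  expect_true(best %in% c("median", "spearman"))
  expect_true(all(tab$selection_frequency > 0))
  # never-selected features do not appear
  sel_any <- unique(unlist(lapply(res[[best]]$importances, names)))
  expect_true(all(tab$feature %in% sel_any))
})
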