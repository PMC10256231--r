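#' Out-of-sample R-squared
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y_{test})^2}, with the
#' test-fold mean in the denominator; may be negative. Undefined (NA) for a
#' constant test fold.
#'
#' @param y_true Observed test values (>= 2).
#' @param y_pred Predicted values.
#' @return The R^2 value, or `NA` when `y_true` is constant.
#' @export
oos_r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Random fold assignment for k-fold cross-validation
#'
#' Uniform random partition into near-equal folds (no stratification).
#'
#' @param n Number of samples.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels 1..n_folds, length n.
#' @export
make_cv_folds <- function(n, n_folds = 10L, seed = 0L) {
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Median-expression feature filter
#'
#' Keeps features whose training-fold median rlog expression is > 0 (the
#' usual midpoint-average median convention for even n).
#'
#' @param X_train Samples x features training matrix (rlog scale).
#' @return Integer indices of the kept features.
#' @export
select_median_expressed <- function(X_train) {
  keep <- unname(which(apply(X_train, 2, stats::median) > 0))
  if (length(keep) == 0) stop("median-expression filter selected no features")
  keep
}

#' Spearman-correlation feature filter
#'
#' Ranks features by the two-sided significance of their Spearman rank
#' correlation with the outcome on the training fold (t approximation on
#' the rank correlation, average ranks for ties), keeps those with BH
#' q <= `q_threshold`, and falls back to raw p <= `p_fallback` when none
#' survive.
#'
#' @param X_train Samples x features training matrix.
#' @param y_train Training outcome.
#' @param q_threshold BH threshold (default 0.01).
#' @param p_fallback Raw-p fallback threshold (default 0.001).
#' @return Integer indices of the kept features.
#' @export
select_spearman <- function(X_train, y_train, q_threshold = 0.01,
                            p_fallback = 0.001) {
  n <- length(y_train)
  ry <- rank(y_train)
  rx <- apply(X_train, 2, rank)
  r <- drop(stats::cor(rx, ry))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- bh_adjust(p)
  keep <- which(q <= q_threshold)
  if (length(keep) == 0) keep <- which(p <= p_fallback)
  if (length(keep) == 0) stop("Spearman filter selected no features")
  keep
}

# centered, Frobenius-normalized Gaussian-kernel Gram matrix of one variable
.hsic_gram <- function(v) {
  n <- length(v)
  s <- stats::sd(v)
  if (s == 0) return(NULL)
  D2 <- outer(v, v, `-`)^2
  K <- exp(-D2 / (2 * s^2))
  H <- diag(n) - 1 / n
  Kc <- H %*% K %*% H
  f <- sqrt(sum(Kc^2))
  if (f == 0) return(NULL)
  Kc / f
}

#' HSIC score of a feature-outcome pair
#'
#' Normalized Hilbert-Schmidt independence criterion
#' \eqn{trace(\bar K_f \bar K_y)/(n-1)^2} with centered, normalized
#' Gaussian-kernel Gram matrices (bandwidth = the variable's SD).
#'
#' @param x Feature values.
#' @param y Outcome values.
#' @return The HSIC score.
#' @export
hsic_score <- function(x, y) {
  Kx <- .hsic_gram(x); Ky <- .hsic_gram(y)
  if (is.null(Kx) || is.null(Ky)) return(NA_real_)
  sum(Kx * Ky) / (length(x) - 1)^2
}

#' HSIC lasso feature selection
#'
#' Kernel-based sparse selection capturing nonlinear dependence: per-feature
#' centered normalized Gaussian Gram matrices are regressed on the outcome
#' Gram matrix under a nonnegative L1 path (solved with glmnet,
#' `lower.limits = 0`), and the features with nonzero weights at the densest
#' solution not exceeding `max_features` are returned. An optional
#' variance-based prefilter reduces the candidates first (the `-5000`
#' suffix convention).
#'
#' @param X_train Samples x features training matrix.
#' @param y_train Training outcome.
#' @param max_features Hard cap on the number of selected features
#'   (default 200).
#' @param prefilter Keep the `prefilter` most variable candidates before
#'   solving (`Inf` = no prefilter).
#' @return Integer indices (into the columns of `X_train`) of the selected
#'   features, ordered by decreasing HSIC-lasso weight.
#' @export
hsic_lasso_select <- function(X_train, y_train, max_features = 200L,
                              prefilter = 5000L) {
  stopifnot(nrow(X_train) >= 5)
  p <- ncol(X_train)
  cand <- seq_len(p)
  if (is.finite(prefilter) && p > prefilter) {
    v <- apply(X_train, 2, stats::var)
    cand <- order(v, decreasing = TRUE)[seq_len(prefilter)]
  }
  Ky <- .hsic_gram(y_train)
  if (is.null(Ky)) stop("constant outcome: HSIC undefined")
  grams <- lapply(cand, function(j) .hsic_gram(X_train[, j]))
  keepc <- !vapply(grams, is.null, logical(1))   # constant features excluded
  cand <- cand[keepc]; grams <- grams[keepc]
  if (length(cand) == 0) return(integer(0))
  if (length(cand) == 1) return(cand)
  n <- nrow(X_train)
  A <- vapply(grams, as.vector, numeric(n * n))
  b <- as.vector(Ky)
  fit <- glmnet::glmnet(A, b, lower.limits = 0, intercept = FALSE,
                        standardize = FALSE, nlambda = 100)
  nz <- fit$df
  ok <- which(nz > 0 & nz <= max_features)
  if (length(ok) == 0) return(integer(0))
  lam_i <- ok[which.max(nz[ok])]
  w <- as.numeric(fit$beta[, lam_i])
  sel <- order(w, decreasing = TRUE)[seq_len(sum(w > 0))]
  cand[sel]
}

#' Elastic-net fit and prediction for one split
#'
#' Standardizes features on the training fold, chooses the mixing parameter
#' (grid 0.1, 0.5, 0.7, 0.9, 0.95, 1) and penalty strength by 4-fold inner
#' cross-validation minimizing MSE, and predicts the test fold.
#'
#' @param X_train,y_train Training data (samples x features).
#' @param X_test Test features.
#' @param seed Seed for the inner fold assignment.
#' @return List: `predictions`, `coefficients` (named, without intercept),
#'   `alpha`, `lambda`.
#' @export
fit_predict_enet <- function(X_train, y_train, X_test, seed = 0L) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  pad <- ncol(X_train) == 1L   # glmnet needs >= 2 columns
  if (pad) {
    X_train <- cbind(X_train, .pad = 0)
    X_test <- cbind(X_test, .pad = 0)
  }
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(X_train, 2, mu), 2, sdv, `/`)
  Xte <- sweep(sweep(X_test, 2, mu), 2, sdv, `/`)
  alphas <- c(0.1, 0.5, 0.7, 0.9, 0.95, 1)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(4), nrow(Xtr)))
  best <- NULL
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(Xtr, y_train, alpha = a, foldid = foldid,
                            nlambda = 100, standardize = FALSE,
                            type.measure = "mse", thresh = 1e-4)
    mse <- min(cv$cvm)
    if (is.null(best) || mse < best$mse)
      best <- list(mse = mse, alpha = a, lambda = cv$lambda.min, cv = cv)
  }
  pred <- drop(stats::predict(best$cv, newx = Xte, s = "lambda.min"))
  cf <- drop(as.matrix(stats::coef(best$cv, s = "lambda.min")))[-1]
  names(cf) <- colnames(X_train)
  if (pad) cf <- cf[-length(cf)]
  list(predictions = unname(pred), coefficients = cf,
       alpha = best$alpha, lambda = best$lambda)
}

#' Random-forest fit and prediction for one split
#'
#' 1000-tree bagged regression forest considering all features at every
#' split; maximum tree depth (grid 1, 2, 5, 10, 20, 50) and minimum leaf
#' size (grid 1, 2, 5) are chosen by out-of-bag error; impurity (gini)
#' importances are returned. Seed-fixed runs are reproducible.
#'
#' @inheritParams fit_predict_enet
#' @param num_trees Number of trees (default 1000).
#' @return List: `predictions`, `importances` (named), `max_depth`,
#'   `min_node_size`, `oob_error`, `oob_grid`.
#' @export
fit_predict_rf <- function(X_train, y_train, X_test, seed = 0L,
                           num_trees = 1000L) {
  dtr <- as.data.frame(X_train)
  names(dtr) <- paste0("f", seq_len(ncol(X_train)))
  dtr$.y <- y_train
  dte <- as.data.frame(X_test)
  names(dte) <- paste0("f", seq_len(ncol(X_test)))
  grid <- expand.grid(max_depth = c(1, 2, 5, 10, 20, 50),
                      min_node = c(1, 2, 5))
  oob <- vapply(seq_len(nrow(grid)), function(i) {
    ranger::ranger(dependent.variable.name = ".y", data = dtr,
                   num.trees = num_trees, mtry = ncol(X_train),
                   max.depth = grid$max_depth[i],
                   min.node.size = grid$min_node[i],
                   replace = TRUE, oob.error = TRUE, num.threads = 1L,
                   seed = seed)$prediction.error
  }, numeric(1))
  bi <- which.min(oob)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dtr,
                        num.trees = num_trees, mtry = ncol(X_train),
                        max.depth = grid$max_depth[bi],
                        min.node.size = grid$min_node[bi],
                        replace = TRUE, oob.error = TRUE,
                        importance = "impurity", num.threads = 1L,
                        seed = seed)
  imp <- fit$variable.importance
  names(imp) <- colnames(X_train)
  list(predictions = unname(stats::predict(fit, dte,
                                           num.threads = 1L)$predictions),
       importances = imp,
       max_depth = grid$max_depth[bi], min_node_size = grid$min_node[bi],
       oob_error = oob[bi], oob_grid = cbind(grid, oob = oob))
}

# run one selector on a training fold; returns feature indices
.apply_selector <- function(selector, X_train, y_train) {
  switch(selector,
         median = select_median_expressed(X_train),
         spearman = select_spearman(X_train, y_train),
         hsic = hsic_lasso_select(X_train, y_train),
         none = seq_len(ncol(X_train)),
         stop("unknown selector: ", selector))
}

#' Repeated cross-validated phenotype prediction
#'
#' The full multi-feature protocol: for each of `n_repeats` random
#' `n_folds`-fold partitions, each fold in turn is held out; feature
#' selection (`median`, `spearman`, `hsic` or `none`) runs on the training
#' plants only, the learner (`enet` or `rf`) is fitted on the selected
#' features and predicts the test fold. Reported are the out-of-sample R^2
#' of every split, the pooled R^2 and Pearson correlation of each repeat's
#' concatenated test predictions, and their medians (the median over the 90
#' splits of the default scheme is the midpoint average of the 45th/46th
#' order statistics). Per-split selected features and importances (absolute
#' enet coefficients or gini importances) are recorded.
#'
#' @param X Samples x features matrix (rlog scale for expression).
#' @param y Outcome vector.
#' @param selector `"median"`, `"spearman"`, `"hsic"` or `"none"`.
#' @param model `"enet"` or `"rf"`.
#' @param n_repeats,n_folds Scheme (defaults 9 and 10 = 90 splits).
#' @param seed Base seed; repeat r uses seed + r - 1.
#' @return Object of class `prediction_result`: `split_r2` (one per
#'   split), `pooled_r2`, `pooled_pcc` (one per repeat), `median_test_r2`,
#'   `median_pooled_r2`, `median_pooled_pcc`, `importances` (list, one
#'   named vector per split), `selection_frequency`, `selector`, `model`.
#' @export
run_repeated_cv <- function(X, y, selector = "median", model = "enet",
                            n_repeats = 9L, n_folds = 10L, seed = 0L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  split_r2 <- numeric(0)
  pooled_r2 <- pooled_pcc <- numeric(n_repeats)
  importances <- list()
  sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))
  n_splits <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- make_cv_folds(n, n_folds, seed + r - 1L)
    pred_all <- obs_all <- numeric(0)
    for (k in seq_len(n_folds)) {
      n_splits <- n_splits + 1L
      te <- which(folds == k); tr <- which(folds != k)
      res <- tryCatch({
        sel <- .apply_selector(selector, X[tr, , drop = FALSE], y[tr])
        if (length(sel) == 0) stop("empty selection")
        Xtr <- X[tr, sel, drop = FALSE]
        Xte <- X[te, sel, drop = FALSE]
        fit <- if (model == "enet")
          fit_predict_enet(Xtr, y[tr], Xte, seed = seed + 100L * n_splits)
        else if (model == "rf")
          fit_predict_rf(Xtr, y[tr], Xte, seed = seed + 100L * n_splits)
        else stop("unknown model: ", model)
        imp <- if (model == "enet") abs(fit$coefficients) else
          fit$importances
        list(pred = fit$predictions, imp = imp, sel = sel)
      }, error = function(e) NULL)
      if (is.null(res)) { split_r2 <- c(split_r2, NA); next }
      split_r2 <- c(split_r2, oos_r2(y[te], res$pred))
      pred_all <- c(pred_all, res$pred); obs_all <- c(obs_all, y[te])
      sel_count[colnames(X)[res$sel]] <-
        sel_count[colnames(X)[res$sel]] + 1
      importances[[n_splits]] <- res$imp
    }
    pooled_r2[r] <- if (length(obs_all) >= 2) oos_r2(obs_all, pred_all)
      else NA_real_
    pooled_pcc[r] <- if (length(obs_all) >= 2)
      stats::cor(obs_all, pred_all) else NA_real_
  }
  structure(list(split_r2 = split_r2, pooled_r2 = pooled_r2,
                 pooled_pcc = pooled_pcc,
                 median_test_r2 = stats::median(split_r2, na.rm = TRUE),
                 median_pooled_r2 = stats::median(pooled_r2, na.rm = TRUE),
                 median_pooled_pcc = stats::median(pooled_pcc, na.rm = TRUE),
                 importances = importances,
                 selection_frequency = sel_count / (n_repeats * n_folds),
                 selector = selector, model = model,
                 n_repeats = n_repeats, n_folds = n_folds, seed = seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Repeated CV prediction (%s selector, %s model)\n",
              x$selector, x$model))
  cat(sprintf("  median test R2:    %.3f  (%d splits)\n",
              x$median_test_r2, length(x$split_r2)))
  cat(sprintf("  median pooled R2:  %.3f\n", x$median_pooled_r2))
  cat(sprintf("  median pooled PCC: %.3f\n", x$median_pooled_pcc))
  invisible(x)
}

#' Permutation baseline for the repeated-CV protocol
#'
#' Trains and tests `n_perm` models on outcome-permuted copies of the data,
#' each on a single random 90/10 train-test split mimicking one fold, with
#' the same selector and model as the real-data run, and returns the
#' permuted R^2 scores and their 95th percentile (linear interpolation on
#' the sorted values). A real result "passes" the star criterion when its
#' median test R^2 exceeds this percentile.
#'
#' @inheritParams run_repeated_cv
#' @param n_perm Number of permuted datasets (default 90).
#' @param test_fraction Held-out fraction per permutation (default 0.1).
#' @return List: `r2_perm` (length `n_perm`), `percentile_95`.
#' @export
permutation_baseline <- function(X, y, selector = "median", model = "enet",
                                 n_perm = 90L, test_fraction = 0.1,
                                 seed = 0L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- length(y)
  n_test <- max(2L, round(test_fraction * n))
  r2 <- vapply(seq_len(n_perm), function(b) {
    set.seed(seed + b)
    yp <- y[sample.int(n)]
    te <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), te)
    out <- tryCatch({
      sel <- .apply_selector(selector, X[tr, , drop = FALSE], yp[tr])
      if (length(sel) == 0) stop("empty selection")
      fit <- if (model == "enet")
        fit_predict_enet(X[tr, sel, drop = FALSE], yp[tr],
                         X[te, sel, drop = FALSE], seed = seed + 7L * b)
      else fit_predict_rf(X[tr, sel, drop = FALSE], yp[tr],
                          X[te, sel, drop = FALSE], seed = seed + 7L * b)
      oos_r2(yp[te], fit$predictions)
    }, error = function(e) NA_real_)
    out
  }, numeric(1))
  list(r2_perm = r2,
       percentile_95 = unname(stats::quantile(r2, 0.95, na.rm = TRUE,
                                              type = 7)))
}

#' Feature-importance ranking across model versions
#'
#' Restricts to the model version (selector) with the highest median test
#' R^2, takes each feature's median importance across the splits in which
#' it was selected (unselected splits are treated as missing, not zero),
#' and reports the selection frequency separately.
#'
#' @param results_by_selector Named list of [run_repeated_cv()] results
#'   (names = selector labels).
#' @param top_k Return at most this many features (default all selected).
#' @return Data frame sorted by decreasing median importance: feature,
#'   median_importance, selection_frequency; the winning selector is
#'   attached as attribute `"best_selector"`.
#' @export
rank_feature_importance <- function(results_by_selector, top_k = Inf) {
  stopifnot(length(results_by_selector) >= 1)
  med_r2 <- vapply(results_by_selector, function(r) r$median_test_r2,
                   numeric(1))
  best <- results_by_selector[[which.max(med_r2)]]
  all_imp <- best$importances
  feats <- unique(unlist(lapply(all_imp, names)))
  rows <- lapply(feats, function(f) {
    vals <- unlist(lapply(all_imp, function(im)
      if (f %in% names(im)) im[[f]] else NULL))
    data.frame(feature = f, median_importance = stats::median(vals),
               selection_frequency =
                 unname(best$selection_frequency[f]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median_importance), ]
  rownames(out) <- NULL
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  attr(out, "best_selector") <- names(results_by_selector)[which.max(med_r2)]
  out
}
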