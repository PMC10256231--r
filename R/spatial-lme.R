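# REML machinery for the two-parameter Gaussian covariogram.
# V(nu, r) = nu * I + (1 - nu) * exp(-(d/r)^2); total variance profiled out.

.reml_neg_loglik <- function(theta, y, X, d) {
  nu <- stats::plogis(theta[1])
  r <- exp(theta[2])
  n <- length(y)
  p <- ncol(X)
  V <- nu * diag(n) + (1 - nu) * exp(-(d / r)^2)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- tryCatch(solve(XtViX, crossprod(X, Vi_y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  res <- y - X %*% beta
  Vi_res <- backsolve(ch, forwardsolve(t(ch), res))
  rss <- drop(crossprod(res, Vi_res))
  if (rss <= 0) return(1e10)
  sigma2 <- rss / (n - p)
  ld_V <- 2 * sum(log(diag(ch)))
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  0.5 * ((n - p) * log(sigma2) + ld_V + as.numeric(ld_X))
}

.reml_extract <- function(theta, y, X, d) {
  nu <- stats::plogis(theta[1])
  r <- exp(theta[2])
  n <- length(y); p <- ncol(X)
  V <- nu * diag(n) + (1 - nu) * exp(-(d / r)^2)
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  res <- y - X %*% beta
  Vi_res <- backsolve(ch, forwardsolve(t(ch), res))
  sigma2 <- drop(crossprod(res, Vi_res)) / (n - p)
  list(beta = drop(beta), sigma2 = sigma2, nugget = nu, range_ = r,
       vcov_beta = sigma2 * solve(XtViX), resid = drop(res))
}

#' Spatial linear mixed model for one feature-phenotype pair
#'
#' Fits \eqn{y = \beta_0 + \beta_1 x + \epsilon},
#' \eqn{\epsilon \sim N(0, \Sigma)} with the Gaussian covariogram
#' \eqn{\Sigma_{ij} = \sigma_\epsilon^2(\nu I_{ij} + (1-\nu)
#' e^{-(d_{ij}/r)^2})} by restricted maximum likelihood: the nugget and
#' range are optimized on an unconstrained (logit, log) scale by
#' Nelder-Mead from the best starts of a coarse grid, with
#' \eqn{(\beta_0, \beta_1, \sigma_\epsilon^2)} profiled out via generalized
#' least squares at each step. The Wald test on \eqn{\beta_1} uses a t
#' reference with n - 2 degrees of freedom. If the REML optimization fails,
#' an ordinary regression is fitted instead and flagged.
#'
#' @param y Phenotype vector (plants with missing values are dropped).
#' @param x Feature vector, typically z-scored across the included plants.
#' @param coords Two-column matrix of field coordinates (metres), rows
#'   aligned with `y`.
#' @param n_starts Number of grid starts refined by Nelder-Mead.
#' @return Object of class `spatial_lme`: `beta` (intercept, slope), `se`,
#'   `sigma2`, `nugget`, `range_`, `wald_stat`, `p`, `df`, `converged`,
#'   `fallback`, `n`.
#' @export
spatial_lme <- function(y, x, coords, n_starts = 5L) {
  coords <- as.matrix(coords)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]; coords <- coords[ok, , drop = FALSE]
  n <- length(y)
  stopifnot(n >= 10)
  if (stats::sd(x) == 0) stop("rank-deficient design: constant feature")
  X <- cbind(1, x)
  d <- as.matrix(stats::dist(coords))
  pos_d <- d[upper.tri(d)]
  r_grid <- stats::median(pos_d) * c(0.25, 1, 3)
  grid <- expand.grid(nu = c(0.1, 0.5, 0.9, 0.99), r = r_grid)
  theta_grid <- cbind(stats::qlogis(grid$nu), log(grid$r))
  vals <- apply(theta_grid, 1, function(th) .reml_neg_loglik(th, y, X, d))
  starts <- theta_grid[order(vals)[seq_len(min(n_starts, nrow(grid)))], ,
                       drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(
      stats::optim(starts[i, ], .reml_neg_loglik, y = y, X = X, d = d,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value < 1e9 &&
        (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    lmfit <- stats::lm(y ~ x)
    sm <- summary(lmfit)$coefficients
    out <- list(beta = stats::coef(lmfit), se = sm[, 2],
                sigma2 = summary(lmfit)$sigma^2,
                nugget = NA_real_, range_ = NA_real_,
                wald_stat = sm[2, 3], p = sm[2, 4], df = n - 2,
                converged = FALSE, fallback = TRUE, n = n)
  } else {
    ex <- .reml_extract(best$par, y, X, d)
    se <- sqrt(diag(ex$vcov_beta))
    tstat <- ex$beta[2] / se[2]
    out <- list(beta = stats::setNames(ex$beta, c("(Intercept)", "x")),
                se = stats::setNames(se, c("(Intercept)", "x")),
                sigma2 = ex$sigma2, nugget = ex$nugget, range_ = ex$range_,
                wald_stat = tstat,
                p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
                df = n - 2, converged = TRUE, fallback = FALSE, n = n)
  }
  class(out) <- "spatial_lme"
  out
}

#' @export
print.spatial_lme <- function(x, ...) {
  cat("Spatial linear mixed model (Gaussian covariogram, REML)\n")
  if (x$fallback) cat("  [ordinary-regression fallback]\n")
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g (se %.3g), Wald t = %.3g, p = %.3g\n",
              x$beta[1], x$beta[2], x$se[2], x$wald_stat, x$p))
  if (!x$fallback)
    cat(sprintf("  sigma2 = %.4g, nugget = %.3g, range = %.3g m, n = %d\n",
                x$sigma2, x$nugget, x$range_, x$n))
  invisible(x)
}

#' @export
coef.spatial_lme <- function(object, ...) object$beta

#' @export
summary.spatial_lme <- function(object, ...) {
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `t value` = object$beta / object$se)
  structure(list(coefficients = tab, p_slope = object$p,
                 nugget = object$nugget, range_ = object$range_,
                 sigma2 = object$sigma2, fallback = object$fallback),
            class = "summary.spatial_lme")
}

#' @export
print.summary.spatial_lme <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("slope p (t, Wald) = %.4g\n", x$p_slope))
  invisible(x)
}

#' @export
predict.spatial_lme <- function(object, newx, ...) {
  # fixed effects only; no conditioning on training residuals
  object$beta[1] + object$beta[2] * newx
}

#' Screen a feature matrix against one phenotype
#'
#' Fits one [spatial_lme()] per feature (columns of `X`, z-scored
#' column-wise first) and BH-adjusts the Wald p-values across features.
#'
#' @param y Phenotype vector over plants.
#' @param X Plants x features matrix.
#' @param coords Field coordinates aligned with `y`.
#' @return Data frame sorted by q: feature, beta1, p, q, fallback; the
#'   number of q <= 0.05 calls is attached as attribute `"n_significant"`.
#' @export
screen_features <- function(y, X, coords) {
  X <- as.matrix(X)
  Xz <- scale(X)
  res <- lapply(seq_len(ncol(X)), function(j) {
    f <- tryCatch(spatial_lme(y, Xz[, j], coords), error = function(e) NULL)
    if (is.null(f))
      return(data.frame(feature = colnames(X)[j], beta1 = NA, p = NA,
                        fallback = NA, stringsAsFactors = FALSE))
    data.frame(feature = colnames(X)[j], beta1 = unname(f$beta[2]),
               p = f$p, fallback = f$fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$q <= 0.05, na.rm = TRUE)
  out
}

#' Cross-validated predictive power of a single feature
#'
#' Scores one feature-phenotype pair with the same repeated k-fold protocol
#' as the multi-feature models (default 9 x 10-fold): per split the spatial
#' LME is fitted on the training plants (feature z-scored on the training
#' fold only) and test plants are predicted from the fixed effects.
#'
#' @inheritParams spatial_lme
#' @param n_repeats,n_folds Cross-validation scheme (default 9 and 10).
#' @param seed Base seed; repeat r uses seed + r - 1 for its fold split.
#' @return A `prediction_result` (see [run_repeated_cv()]) without
#'   importance tables.
#' @export
cv_score_single_feature <- function(y, x, coords, n_repeats = 9L,
                                    n_folds = 10L, seed = 0L) {
  coords <- as.matrix(coords)
  n <- length(y)
  split_r2 <- numeric(0)
  pooled_r2 <- pooled_pcc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- make_cv_folds(n, n_folds, seed + r - 1L)
    pred_all <- obs_all <- numeric(0)
    for (k in seq_len(n_folds)) {
      te <- which(folds == k); tr <- which(folds != k)
      mu <- mean(x[tr]); sdv <- stats::sd(x[tr])
      if (sdv == 0) { split_r2 <- c(split_r2, NA); next }
      xz_tr <- (x[tr] - mu) / sdv
      xz_te <- (x[te] - mu) / sdv
      fit <- tryCatch(spatial_lme(y[tr], xz_tr, coords[tr, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) { split_r2 <- c(split_r2, NA); next }
      pred <- predict(fit, xz_te)
      split_r2 <- c(split_r2, oos_r2(y[te], pred))
      pred_all <- c(pred_all, pred); obs_all <- c(obs_all, y[te])
    }
    pooled_r2[r] <- oos_r2(obs_all, pred_all)
    pooled_pcc[r] <- stats::cor(obs_all, pred_all)
  }
  structure(list(split_r2 = split_r2, pooled_r2 = pooled_r2,
                 pooled_pcc = pooled_pcc,
                 median_test_r2 = stats::median(split_r2, na.rm = TRUE),
                 median_pooled_r2 = stats::median(pooled_r2, na.rm = TRUE),
                 median_pooled_pcc = stats::median(pooled_pcc, na.rm = TRUE),
                 selector = "single_feature", model = "spatial_lme"),
            class = "prediction_result")
}
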