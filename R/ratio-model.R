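#' Conditional log-link model for a ratio phenotype
#'
#' Models a ratio phenotype's numerator given its denominator:
#' \eqn{\ln E(n \oslash d) = \beta_0 + \beta_1 x}, i.e.
#' \eqn{n \sim N(d \exp(\beta_0 + \beta_1 x), \Sigma)}, optionally with an
#' offset \eqn{\ln E((c + n) \oslash d) = \beta_0 + \beta_1 x} (fitted mean
#' \eqn{d \exp(\beta_0+\beta_1 x) - c}, constrained so fitted numerators
#' stay non-negative, c >= 0 initialized at 0). Four error structures are
#' supported: constant variance; spatial (Gaussian covariogram over field
#' coordinates); heteroscedastic with the variance increasing linearly in
#' the fitted mean (\eqn{Var_i = \sigma^2 \hat\mu_i}); or both. The scale
#' \eqn{\sigma^2} is profiled out of the normal likelihood; the remaining
#' parameters are optimized numerically and the Wald p for \eqn{\beta_1}
#' uses the observed information with a t reference (n - 2 df).
#'
#' @param num Numerator values (>= 0).
#' @param den Denominator values (> 0).
#' @param x Feature (e.g. a gene's expression) across plants.
#' @param coords Field coordinates, required for the spatial structures.
#' @param error_structure One of `"constant"`, `"spatial"`,
#'   `"heteroscedastic"`, `"spatial_heteroscedastic"`.
#' @param with_offset Fit the offset variant (for ratios whose value decays
#'   with the denominator).
#' @return Object of class `ratio_loglink`: `beta0`, `beta1`, `offset_c`,
#'   `sigma2`, `nugget`, `range_`, `p`, `logLik`, `fitted`, `converged`,
#'   `error_structure`.
#' @export
ratio_loglink <- function(num, den, x, coords = NULL,
                          error_structure = c("constant", "spatial",
                                              "heteroscedastic",
                                              "spatial_heteroscedastic"),
                          with_offset = FALSE) {
  error_structure <- match.arg(error_structure)
  stopifnot(length(num) == length(den), length(x) == length(num),
            all(den > 0), all(num >= 0))
  spatial <- error_structure %in% c("spatial", "spatial_heteroscedastic")
  hetero <- error_structure %in% c("heteroscedastic",
                                   "spatial_heteroscedastic")
  if (spatial) {
    stopifnot(!is.null(coords))
    d <- as.matrix(stats::dist(as.matrix(coords)))
    r_init <- stats::median(d[upper.tri(d)])
  }
  n <- length(num)

  # parameter vector: beta0, beta1 [, sqrt_c ] [, logit nu, log r ];
  # c = sqrt_c^2 keeps the offset non-negative with 0 reachable
  unpack <- function(par) {
    i <- 2L
    out <- list(beta0 = par[1], beta1 = par[2], c = 0)
    if (with_offset) { i <- i + 1L; out$c <- par[i]^2 }
    if (spatial) {
      out$nu <- stats::plogis(par[i + 1L])
      out$r <- exp(par[i + 2L])
    }
    out
  }
  nll <- function(par) {
    p <- unpack(par)
    mu <- den * exp(p$beta0 + p$beta1 * x) - p$c
    if (any(mu < 0) || any(!is.finite(mu))) return(1e10)
    res <- num - mu
    if (hetero) {
      wdiag <- pmax(mu, 1e-8)
      res_w <- res / sqrt(wdiag)
      ld_w <- sum(log(wdiag))
    } else {
      res_w <- res
      ld_w <- 0
    }
    if (spatial) {
      V <- p$nu * diag(n) + (1 - p$nu) * exp(-(d / p$r)^2)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      z <- forwardsolve(t(ch), res_w)
      rss <- sum(z^2)
      ld <- 2 * sum(log(diag(ch))) + ld_w
    } else {
      rss <- sum(res_w^2)
      ld <- ld_w
    }
    if (rss <= 0) return(1e10)
    sigma2 <- rss / n
    0.5 * (n * log(sigma2) + ld + n)
  }

  par0 <- c(log(mean(num / den)), 0)
  if (with_offset) par0 <- c(par0, 0)            # sqrt_c = 0 -> c = 0
  if (spatial) par0 <- c(par0, stats::qlogis(0.7), log(r_init))
  op <- tryCatch(
    stats::optim(par0, nll, method = "Nelder-Mead", hessian = TRUE,
                 control = list(reltol = 1e-12, maxit = 2000)),
    error = function(e) NULL)
  conv <- !is.null(op) && is.finite(op$value) && op$value < 1e9
  if (!conv)
    return(structure(list(converged = FALSE,
                          error_structure = error_structure),
                     class = "ratio_loglink"))
  p <- unpack(op$par)
  mu <- den * exp(p$beta0 + p$beta1 * x) - p$c
  res <- num - mu
  if (hetero) {
    rss <- sum(res^2 / pmax(mu, 1e-8))
  } else rss <- sum(res^2)
  se1 <- tryCatch(sqrt(diag(solve(op$hessian))[2]), error = function(e) NA)
  tstat <- p$beta1 / se1
  pval <- if (is.finite(tstat))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE) else NA_real_
  structure(list(beta0 = p$beta0, beta1 = p$beta1, offset_c = p$c,
                 sigma2 = rss / n,
                 nugget = if (spatial) p$nu else NA_real_,
                 range_ = if (spatial) p$r else NA_real_,
                 se_beta1 = se1, wald_stat = tstat, p = pval,
                 logLik = -op$value - 0.5 * n * log(2 * pi),
                 fitted = mu, residuals = res, converged = TRUE,
                 error_structure = error_structure, n = n),
            class = "ratio_loglink")
}

#' @export
print.ratio_loglink <- function(x, ...) {
  cat(sprintf("Conditional log-link ratio model (%s errors)\n",
              x$error_structure))
  if (!x$converged) { cat("  did not converge\n"); return(invisible(x)) }
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g (p = %.3g), offset c = %.3g\n",
              x$beta0, x$beta1, x$p, x$offset_c))
  cat(sprintf("  logLik = %.4g, n = %d\n", x$logLik, x$n))
  invisible(x)
}

#' @export
coef.ratio_loglink <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, c = object$offset_c)
}

#' @export
logLik.ratio_loglink <- function(object, ...) object$logLik
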