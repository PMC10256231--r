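#' Coefficient of variation (percent)
#'
#' `100 * sd/mean` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' MAD-rule outlier mask
#'
#' Flags values more than 3 scaled median absolute deviations from the
#' median, with scaled MAD = 1.4826 * median(|x - median|). When the scaled
#' MAD is zero (over half the values identical), any value differing from
#' the median is flagged — the limit-consistent extension of the rule.
#'
#' @param values Numeric vector, length >= 3.
#' @return Logical mask, `TRUE` = outlier.
#' @export
detect_outliers <- function(values) {
  stopifnot(length(values) >= 3)
  med <- stats::median(values)
  smad <- 1.4826 * stats::median(abs(values - med))
  if (smad == 0) values != med else abs(values - med) > 3 * smad
}

#' Fit the mean-CV^2 trend of gene expression
#'
#' Fits \eqn{CV^2(x) = a/\bar x + b} to per-gene squared coefficients of
#' variation against mean expression with a gamma-family GLM (identity
#' link), omitting genes expressed (normalized count > 0) in fewer than
#' `min_samples_expressed` samples. CV^2 here is dimensionless (fractional),
#' not percent. On GLM non-convergence the fit falls back to robust least
#' squares on (1/mean, CV^2) with a warning.
#'
#' @param normalized_counts Genes x plants matrix of normalized counts
#'   (e.g. [batch_normalized_counts()]).
#' @param min_samples_expressed Minimum number of samples with a positive
#'   count for a gene to enter the trend fit (default 10).
#' @return Object of class `cv_trend`: `a`, `b`, `min_samples_expressed`,
#'   `stats` (per eligible gene: mean, cv2), `method`.
#' @export
fit_cv_trend <- function(normalized_counts, min_samples_expressed = 10) {
  X <- as.matrix(normalized_counts)
  expressed <- rowSums(X > 0) >= min_samples_expressed
  if (sum(expressed) < 10)
    stop("fewer than 10 genes eligible for the CV trend fit")
  X <- X[expressed, , drop = FALSE]
  m <- rowMeans(X)
  cv2 <- apply(X, 1, stats::var) / m^2
  df <- data.frame(mean = m, cv2 = cv2, inv_mean = 1 / m)
  fit <- tryCatch(
    withCallingHandlers(
      stats::glm(cv2 ~ inv_mean, data = df,
                 family = stats::Gamma(link = "identity"),
                 start = c(max(min(cv2), 1e-4), 1)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    cf <- stats::coef(fit)
    method <- "gamma_glm"
  } else {
    warning("gamma GLM did not converge; falling back to robust LS")
    rf <- stats::lm(cv2 ~ inv_mean, data = df,
                    weights = 1 / pmax(cv2, 1e-8)^2)
    cf <- stats::coef(rf)
    method <- "robust_ls"
  }
  structure(list(a = unname(cf[2]), b = unname(cf[1]),
                 min_samples_expressed = min_samples_expressed,
                 stats = df[, c("mean", "cv2")], method = method),
            class = "cv_trend")
}

#' @export
print.cv_trend <- function(x, ...) {
  cat(sprintf("Mean-CV^2 trend: CV^2 = %.4g/mean + %.4g  (%s, %d genes)\n",
              x$a, x$b, x$method, nrow(x$stats)))
  invisible(x)
}

#' @export
predict.cv_trend <- function(object, mean_expression, ...) {
  object$a / mean_expression + object$b
}

#' Normalized CV against the mean-CV^2 trend
#'
#' \eqn{normCV(x) = \log_2(CV^2(x) / trend(\bar x))}: how much more (or
#' less) variable a gene is than expected at its expression level.
#'
#' @param cv2 Per-gene squared (fractional) CV.
#' @param mean_expression Per-gene mean normalized expression.
#' @param trend A [fit_cv_trend()] object.
#' @return Per-gene normCV values.
#' @export
norm_cv <- function(cv2, mean_expression, trend) {
  stopifnot(inherits(trend, "cv_trend"))
  tv <- predict(trend, mean_expression)
  if (any(tv <= 0)) stop("non-positive trend value")
  log2(cv2 / tv)
}

#' Normality screen (Shapiro-Wilk + Anderson-Darling)
#'
#' Runs both tests and reports a pass flag at p > 0.01 for both — the
#' screen used to call a phenotype "approximately normal".
#'
#' @param values Numeric vector, length >= 8, non-constant.
#' @return List: `shapiro_p`, `anderson_p`, `anderson_stat`,
#'   `pass_at_0.01`.
#' @export
normality_screen <- function(values) {
  stopifnot(length(values) >= 8)
  if (stats::sd(values) == 0) stop("constant data: normality tests undefined")
  sw <- stats::shapiro.test(values)
  ad <- nortest::ad.test(values)
  list(shapiro_p = sw$p.value, anderson_p = ad$p.value,
       anderson_stat = unname(ad$statistic),
       pass_at_0.01 = sw$p.value > 0.01 && ad$p.value > 0.01)
}

#' Per-gene and per-phenotype variability report
#'
#' Convenience wrapper producing the standard variability tables: per gene
#' (mean, CV percent, fractional CV^2, normCV) on normalized counts, and per
#' phenotype (CV with and without MAD outliers, normality flags with and
#' without outliers).
#'
#' @param normalized_counts Genes x plants normalized count matrix.
#' @param phenotypes Data frame of numeric phenotypes (plants in rows).
#' @param min_samples_expressed Trend eligibility threshold.
#' @return List: `genes` (data frame), `phenotypes` (data frame), `trend`.
#' @export
variability_report <- function(normalized_counts, phenotypes = NULL,
                               min_samples_expressed = 10) {
  X <- as.matrix(normalized_counts)
  trend <- fit_cv_trend(X, min_samples_expressed)
  m <- rowMeans(X)
  v <- apply(X, 1, stats::var)
  cv2 <- ifelse(m > 0, v / m^2, NA)
  eligible <- rowSums(X > 0) >= min_samples_expressed
  genes <- data.frame(gene = rownames(X), mean = m, cv = 100 * sqrt(cv2),
                      cv2 = cv2,
                      norm_cv = ifelse(eligible, norm_cv(cv2, m, trend), NA),
                      eligible = eligible, stringsAsFactors = FALSE)
  ph <- NULL
  if (!is.null(phenotypes)) {
    num <- vapply(phenotypes, is.numeric, logical(1))
    ph <- do.call(rbind, lapply(names(phenotypes)[num], function(nm) {
      y <- phenotypes[[nm]]
      y <- y[is.finite(y)]
      out <- detect_outliers(y)
      yo <- y[!out]
      norm_all <- tryCatch(normality_screen(y)$pass_at_0.01,
                           error = function(e) NA)
      norm_no <- tryCatch(normality_screen(yo)$pass_at_0.01,
                          error = function(e) NA)
      data.frame(phenotype = nm,
                 cv = coefficient_of_variation(y),
                 cv_no_outliers = if (length(yo) >= 2 && mean(yo) != 0)
                   coefficient_of_variation(yo) else NA,
                 n_outliers = sum(out),
                 normal = norm_all, normal_no_outliers = norm_no,
                 stringsAsFactors = FALSE)
    }))
  }
  list(genes = genes, phenotypes = ph, trend = trend)
}
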