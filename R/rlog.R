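#' Median-of-ratios library size factors
#'
#' Per-sample size factor: the median across genes of the ratio of the
#' sample's count to the gene's geometric mean, using genes with nonzero
#' counts in every sample; factors are rescaled to geometric mean 1. If no
#' gene is expressed in all samples, a positive-count-only variant is used
#' (geometric means and ratios computed over positive entries per gene).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named vector of positive size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    lgm <- rowMeans(log(counts[allpos, , drop = FALSE]))
    s <- apply(counts[allpos, , drop = FALSE], 2,
               function(k) exp(stats::median(log(k) - lgm)))
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    lgm <- rowMeans(lc, na.rm = TRUE)
    s <- apply(lc, 2, function(k) exp(stats::median(k - lgm, na.rm = TRUE)))
  }
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

#' Method-of-moments NB dispersion estimates
#'
#' Per-gene dispersion \eqn{\alpha_i} of the negative binomial
#' (Var = mu + alpha mu^2), estimated on size-factor-normalized counts by
#' moments and floored at `floor_value`; genes with sub-Poisson variance get
#' the floor. An optional per-gene maximum-likelihood refinement maximizes
#' the NB likelihood at moment means.
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Per-sample size factors
#'   (default [estimate_size_factors()]).
#' @param refine_mle If `TRUE`, refine each estimate by 1-D likelihood
#'   maximization over log alpha.
#' @param floor_value Lower bound on alpha.
#' @return Named vector of dispersions.
#' @export
estimate_dispersions <- function(counts, size_factors = NULL,
                                 refine_mle = FALSE, floor_value = 1e-8) {
  counts <- as.matrix(counts)
  s <- size_factors %||% estimate_size_factors(counts)
  norm <- sweep(counts, 2, s, `/`)
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  # normalized Poisson noise contributes mu * mean(1/s) to the variance
  alpha <- (v - m * mean(1 / s)) / m^2
  alpha[!is.finite(alpha)] <- floor_value
  alpha <- pmax(alpha, floor_value)
  if (refine_mle) {
    for (i in seq_len(nrow(counts))) {
      if (m[i] <= 0) next
      mu <- m[i] * s
      nll <- function(la) -sum(stats::dnbinom(counts[i, ], mu = mu,
                                              size = exp(-la), log = TRUE))
      opt <- stats::optimize(nll, c(log(floor_value), log(100)))
      alpha[i] <- max(exp(opt$minimum), floor_value)
    }
  }
  stats::setNames(alpha, rownames(counts))
}

# design matrix: intercept + non-reference batch dummies + all plant dummies
.rlog_design <- function(meta, ref_batch) {
  batches <- sort(unique(meta$batch))
  plants <- sort(unique(meta$plant_id))
  nb <- setdiff(batches, ref_batch)
  X <- cbind(intercept = rep(1, nrow(meta)))
  for (b in nb) X <- cbind(X, as.numeric(meta$batch == b))
  for (p in plants) X <- cbind(X, as.numeric(meta$plant_id == p))
  colnames(X) <- c("intercept", paste0("batch_", nb, recycle0 = TRUE),
                   paste0("plant_", plants))
  list(X = X, batches = batches, nonref = nb, plants = plants)
}

# penalized NB fit for one gene on the log2 link; lambda is the per-column
# ridge weight (0 for flat-prior columns). Returns beta and convergence flag.
.fit_gene_nb <- function(k, s, alpha, X, lambda, tol = 1e-8, maxit = 100L) {
  ln2 <- log(2)
  beta <- numeric(ncol(X))
  beta[1] <- log2(mean(k / s) + 0.5)
  pll <- function(beta) {
    mu <- s * 2^(drop(X %*% beta))
    sum(k * log(mu) - (k + 1 / alpha) * log(mu + 1 / alpha)) -
      sum(lambda * beta^2) / 2
  }
  f_old <- pll(beta)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    mu <- s * 2^(drop(X %*% beta))
    g <- ln2 * (k - mu) / (1 + alpha * mu)
    w <- ln2^2 * mu / (1 + alpha * mu)
    grad <- drop(crossprod(X, g)) - lambda * beta
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + lambda + 1e-12
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    t_ <- 1
    repeat {
      beta_new <- beta + t_ * step
      f_new <- pll(beta_new)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    if (t_ < 1e-10) break
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    f_old <- f_new
    if (moved < tol) { conv <- TRUE; break }
  }
  list(beta = beta, converged = conv)
}

#' Regularized-log (rlog) normalization with batch effects and shrunken
#' plant effects
#'
#' Fits, per gene, the negative-binomial regression
#' \eqn{k_{ij} \sim NB(s_j q_{ij}, \alpha_i)},
#' \eqn{\log_2 q_{ij} = x_j \cdot \beta_i}, where the predictor vector holds
#' an intercept, dummies for the non-reference sequencing batches, and a
#' dummy for every plant. The intercept and batch coefficients carry a flat
#' prior; the plant coefficients carry a zero-centered normal prior whose
#' variance is estimated once, globally, by matching an upper quantile of
#' the absolute unshrunken per-plant log2 fold changes (computed relative to
#' the mean of each batch) to the same quantile of a zero-mean normal.
#' Technical repeats of a plant share one plant coefficient, so the fit
#' pools their information while estimating dispersion from all samples.
#'
#' Genes with zero counts in all samples must be removed beforehand; no
#' other prefiltering is applied.
#'
#' @param counts Genes x samples integer matrix (no all-zero rows).
#' @param meta Data frame with columns `sample_id`, `plant_id`, `batch`,
#'   rows in the column order of `counts`.
#' @param size_factors,dispersions Optional; estimated when `NULL`.
#' @param ref_batch Reference batch absorbed in the intercept (default: the
#'   largest batch).
#' @param prior_var Plant-effect prior variance (log2 scale); `NULL` =
#'   estimate by quantile matching. `0` collapses all plant effects;
#'   `Inf` gives an (essentially) unpenalized fit.
#' @param prior_quantile Quantile used in the matching (default 0.95).
#' @return Object of class `rlog_fit`: `beta0`, `batch_log2` (genes x
#'   batches, reference column 0), `plant_effects` (genes x plants),
#'   `prior_var`, `size_factors`, `dispersions`, `converged`,
#'   `fallback` flags, `meta`, `ref_batch`.
#' @export
rlog_fit <- function(counts, meta, size_factors = NULL, dispersions = NULL,
                     ref_batch = NULL, prior_var = NULL,
                     prior_quantile = 0.95) {
  counts <- as.matrix(counts)
  stopifnot(nrow(meta) == ncol(counts),
            all(c("sample_id", "plant_id", "batch") %in% colnames(meta)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("remove genes with zero counts in all samples before fitting")
  s <- size_factors %||% estimate_size_factors(counts)
  alpha <- dispersions %||% estimate_dispersions(counts, s)
  ref_batch <- ref_batch %||% names(which.max(table(meta$batch)))
  des <- .rlog_design(meta, ref_batch)
  X <- des$X
  n_b <- length(des$nonref)
  plant_cols <- seq(2 + n_b, ncol(X))

  if (is.null(prior_var)) {
    norm <- sweep(counts, 2, s, `/`)
    bm <- vapply(des$batches, function(b)
      rowMeans(norm[, meta$batch == b, drop = FALSE]), numeric(nrow(counts)))
    lfc_s <- log2((norm + 0.5) / (bm[, match(meta$batch, des$batches)] + 0.5))
    lfc_p <- vapply(des$plants, function(p)
      rowMeans(lfc_s[, meta$plant_id == p, drop = FALSE]),
      numeric(nrow(counts)))
    qq <- stats::quantile(abs(lfc_p), prior_quantile, names = FALSE)
    prior_var <- (qq / stats::qnorm(1 - (1 - prior_quantile) / 2))^2
    prior_var <- max(prior_var, 1e-6)
  }
  lam_plant <- if (prior_var == 0) Inf else max(1 / prior_var, 1e-8)

  G <- nrow(counts)
  beta0 <- numeric(G)
  batch_log2 <- matrix(0, G, length(des$batches),
                       dimnames = list(rownames(counts), des$batches))
  plant_eff <- matrix(0, G, length(des$plants),
                      dimnames = list(rownames(counts), des$plants))
  converged <- fallback <- logical(G)

  if (is.infinite(lam_plant)) {
    # zero prior variance: plant effects exactly 0; fit intercept + batch
    Xr <- X[, seq_len(1 + n_b), drop = FALSE]
    for (i in seq_len(G)) {
      f <- .fit_gene_nb(counts[i, ], s, alpha[i], Xr, rep(0, ncol(Xr)))
      beta0[i] <- f$beta[1]
      if (n_b > 0) batch_log2[i, des$nonref] <- f$beta[1 + seq_len(n_b)]
      converged[i] <- f$converged
    }
  } else {
    lambda <- rep(0, ncol(X))
    lambda[plant_cols] <- lam_plant
    Xr <- X[, seq_len(1 + n_b), drop = FALSE]
    for (i in seq_len(G)) {
      f <- .fit_gene_nb(counts[i, ], s, alpha[i], X, lambda)
      if (!f$converged) {
        # fall back to the unpenalized batch-only fit, plant effects at 0
        fr <- .fit_gene_nb(counts[i, ], s, alpha[i], Xr, rep(0, ncol(Xr)),
                           maxit = 200L)
        beta0[i] <- fr$beta[1]
        if (n_b > 0) batch_log2[i, des$nonref] <- fr$beta[1 + seq_len(n_b)]
        fallback[i] <- TRUE
        converged[i] <- fr$converged
      } else {
        beta0[i] <- f$beta[1]
        if (n_b > 0) batch_log2[i, des$nonref] <- f$beta[1 + seq_len(n_b)]
        plant_eff[i, ] <- f$beta[plant_cols]
        converged[i] <- TRUE
      }
    }
  }
  structure(list(beta0 = stats::setNames(beta0, rownames(counts)),
                 batch_log2 = batch_log2, plant_effects = plant_eff,
                 prior_var = prior_var, size_factors = s,
                 dispersions = alpha, converged = converged,
                 fallback = fallback, meta = meta, ref_batch = ref_batch),
            class = "rlog_fit")
}

#' @export
print.rlog_fit <- function(x, ...) {
  cat(sprintf("rlog fit: %d genes, %d samples, %d plants, %d batches (ref %s)\n",
              length(x$beta0), nrow(x$meta),
              ncol(x$plant_effects), ncol(x$batch_log2), x$ref_batch))
  cat(sprintf("  plant-effect prior variance: %.4g (log2 scale)\n",
              x$prior_var))
  if (any(x$fallback))
    cat(sprintf("  %d gene(s) used the unpenalized fallback\n",
                sum(x$fallback)))
  invisible(x)
}

#' @export
coef.rlog_fit <- function(object, ...) {
  cbind(intercept = object$beta0, object$batch_log2)
}

#' rlog expression matrix (genes x plants)
#'
#' The regularized-log value of gene i for plant p is
#' \eqn{\beta_{i0} + \beta_{ip}}: library-size and batch effects are removed
#' by construction and technical repeats are united into one estimate.
#'
#' @param fit An [rlog_fit()] object.
#' @return Numeric matrix, genes x plants.
#' @export
rlog_matrix <- function(fit) {
  stopifnot(inherits(fit, "rlog_fit"))
  fit$beta0 + fit$plant_effects
}

#' Batch- and library-size-corrected counts
#'
#' \eqn{x_{ij} = k_{ij} / (b_i^{(batch_j)} s_j)} with the count-scale batch
#' factor \eqn{b_i = 2^{\beta_i^{batch}}} (1 for the reference batch);
#' technical repeats are collapsed by arithmetic averaging. Unlike the rlog
#' matrix this stays on the count scale (used for CV analysis).
#'
#' @param counts The count matrix the model was fitted on.
#' @param fit An [rlog_fit()] object.
#' @return Numeric matrix, genes x plants.
#' @export
batch_normalized_counts <- function(counts, fit) {
  stopifnot(inherits(fit, "rlog_fit"))
  counts <- as.matrix(counts)
  meta <- fit$meta
  bfac <- 2^fit$batch_log2[, match(meta$batch, colnames(fit$batch_log2)),
                           drop = FALSE]
  x <- counts / bfac
  x <- sweep(x, 2, fit$size_factors, `/`)
  plants <- colnames(fit$plant_effects)
  out <- vapply(plants, function(p)
    rowMeans(x[, meta$plant_id == p, drop = FALSE]), numeric(nrow(x)))
  out <- matrix(out, nrow(x), length(plants),
                dimnames = list(rownames(counts), plants))
  out
}
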