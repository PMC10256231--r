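#' Spatial weight matrix over field plants
#'
#' Queen mode: plants whose grid positions differ by at most 1 in both row
#' and column (and are not identical) are connected with weight 1 — i.e.
#' horizontal, vertical and diagonal neighbours. Inverse-distance mode:
#' \eqn{C_{ij} = 1/d_{ij}} with zero diagonal (not row-standardized).
#' Weights are restricted to the requested plants, so the matrix can differ
#' between phenotypes when availability differs.
#'
#' @param design A [make_field_design()] object.
#' @param mode `"queen"` or `"inverse_distance"`.
#' @param plants Plant ids to include (default: the analysis set).
#' @return Object of class `spatial_weights`: list with `C` (n x n), `w`
#'   (sum of entries), `mode`, `plants`.
#' @export
build_spatial_weights <- function(design, mode = c("queen",
                                                   "inverse_distance"),
                                  plants = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "field_design"))
  pos <- design$positions
  plants <- plants %||% pos$plant_id[pos$analysis]
  stopifnot(length(plants) >= 2, all(plants %in% pos$plant_id))
  pos <- pos[match(plants, pos$plant_id), ]
  if (mode == "queen") {
    dr <- abs(outer(pos$row, pos$row, `-`))
    dc <- abs(outer(pos$col, pos$col, `-`))
    C <- (dr <= 1 & dc <= 1) * 1
    diag(C) <- 0
  } else {
    d <- as.matrix(stats::dist(cbind(pos$x, pos$y)))
    C <- 1 / d
    diag(C) <- 0
  }
  dimnames(C) <- list(plants, plants)
  if (any(rowSums(C) == 0))
    warning("plant(s) with no neighbours kept with zero weight row: ",
            paste(plants[rowSums(C) == 0], collapse = ", "))
  structure(list(C = C, w = sum(C), mode = mode, plants = plants),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights (%s): %d plants, total weight %.4g\n",
              x$mode, length(x$plants), x$w))
  invisible(x)
}

#' Global Moran's I
#'
#' \deqn{I = \frac{n}{w} \frac{(x-\bar x)^T C (x-\bar x)}{\|x-\bar x\|^2}}
#' with `C` the connectivity matrix and `w` the sum of its entries.
#'
#' @param x Per-plant values, aligned with `weights$plants` (named vectors
#'   are reordered by name).
#' @param weights A [build_spatial_weights()] object.
#' @return The Moran statistic.
#' @export
morans_i <- function(x, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!is.null(names(x))) x <- x[weights$plants]
  stopifnot(length(x) == length(weights$plants), all(is.finite(x)))
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("zero variance: Moran's I undefined for constant input")
  (length(x) / weights$w) * drop(crossprod(z, weights$C %*% z)) / ss
}

#' Permutation test for Moran's I
#'
#' Recomputes the statistic on `n_perm` random permutations of `x` to form
#' an empirical null; the pseudo p-value is
#' \eqn{(1 + \#\{I_{perm} \ge I_{obs}\})/(1 + n_{perm})} for the upper
#' (positive autocorrelation) tail, or twice the smaller tail (capped at 1)
#' when `alternative = "two.sided"`. Deterministic given `seed`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List: `I`, `p_perm`, `n_perm`, `alternative`.
#' @export
moran_permutation_test <- function(x, weights, n_perm = 999L, seed = 1L,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 99)
  if (!is.null(names(x))) x <- x[weights$plants]
  i_obs <- morans_i(x, weights)
  z <- x - mean(x)
  ss <- sum(z^2)
  n <- length(x)
  set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(b) z[sample.int(n)], numeric(n))
  i_perm <- (n / weights$w) * colSums(Z * (weights$C %*% Z)) / ss
  p_up <- (1 + sum(i_perm >= i_obs)) / (1 + n_perm)
  p <- if (alternative == "greater") p_up else {
    p_lo <- (1 + sum(i_perm <= i_obs)) / (1 + n_perm)
    min(1, 2 * min(p_up, p_lo))
  }
  list(I = i_obs, p_perm = p, n_perm = n_perm, alternative = alternative)
}

#' Parametric (normality-based) test for Moran's I
#'
#' Under the null of no autocorrelation, \eqn{E[I] = -1/(n-1)} and the
#' closed-form normality variance uses
#' \eqn{S_1 = \frac12 \sum_{ij} (c_{ij}+c_{ji})^2},
#' \eqn{S_2 = \sum_i (\sum_j c_{ij} + \sum_j c_{ji})^2}:
#' \deqn{Var[I] = \frac{n^2 S_1 - n S_2 + 3w^2}{(n^2-1) w^2} - E[I]^2.}
#' The p-value is two-sided from the normal approximation.
#'
#' @inheritParams morans_i
#' @return List: `I`, `p_param`, `expected`, `variance`.
#' @export
moran_parametric_test <- function(x, weights) {
  if (!is.null(names(x))) x <- x[weights$plants]
  n <- length(x)
  stopifnot(n >= 4)
  i_obs <- morans_i(x, weights)
  C <- weights$C
  w <- weights$w
  s1 <- 0.5 * sum((C + t(C))^2)
  s2 <- sum((rowSums(C) + colSums(C))^2)
  ei <- -1 / (n - 1)
  vi <- (n^2 * s1 - n * s2 + 3 * w^2) / ((n^2 - 1) * w^2) - ei^2
  if (vi <= .Machine$double.eps^0.5) {
    # complete graphs make I constant (= E[I]); the test is degenerate
    if (abs(i_obs - ei) < 1e-10)
      return(list(I = i_obs, p_param = 1, expected = ei, variance = max(vi, 0)))
    stop("non-positive Moran variance: pathological weights")
  }
  p <- 2 * stats::pnorm(abs(i_obs - ei) / sqrt(vi), lower.tail = FALSE)
  list(I = i_obs, p_param = min(p, 1), expected = ei, variance = vi)
}

#' Moran's I screen over a feature matrix
#'
#' Runs the permutation and parametric tests on every row of a features x
#' plants matrix, dropping plants with missing values per feature and
#' rebuilding the weights on the reduced set, then BH-adjusts each p-value
#' family across features.
#'
#' @param X Features x plants matrix (rownames = feature ids, colnames =
#'   plant ids).
#' @param design A [make_field_design()] object.
#' @param mode Weight mode, see [build_spatial_weights()].
#' @param n_perm Permutations per feature.
#' @param seed Integer seed (feature-specific seeds derive from it).
#' @param parametric Also compute the parametric test (default TRUE).
#' @return Data frame: id, I, p_perm, q_perm and (optionally) p_param,
#'   q_param.
#' @export
moran_screen <- function(X, design, mode = "queen", n_perm = 999L,
                         seed = 1L, parametric = TRUE) {
  X <- as.matrix(X)
  base_w <- build_spatial_weights(design, mode, plants = colnames(X))
  res <- lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    ok <- is.finite(x)
    w <- if (all(ok)) base_w else
      build_spatial_weights(design, mode, plants = colnames(X)[ok])
    if (stats::sd(x[ok]) == 0)
      return(c(I = NA, p_perm = NA, p_param = NA))
    pt <- moran_permutation_test(x[ok], w, n_perm,
                                 seed = substream_seed(seed, rownames(X)[i]))
    pp <- if (parametric) moran_parametric_test(x[ok], w)$p_param else NA
    c(I = pt$I, p_perm = pt$p_perm, p_param = pp)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(id = rownames(X), I = res$I, p_perm = res$p_perm,
                    q_perm = bh_adjust(res$p_perm),
                    stringsAsFactors = FALSE)
  if (parametric) {
    out$p_param <- res$p_param
    out$q_param <- bh_adjust(res$p_param)
  }
  out
}
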