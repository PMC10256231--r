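#' Lay out a single-plant field trial grid
#'
#' Creates the planting layout of a regular field trial: `n_rows` x `n_cols`
#' positions with `spacing` metres between adjacent rows and columns. Border
#' positions (first/last row or column) are flagged; a random fraction of the
#' interior positions is marked missing (emergence failure). The analysis set
#' — the plants that are profiled and phenotyped — consists of the non-border,
#' non-missing positions, mirroring common practice of discarding border
#' plants that experience different competition.
#'
#' Plant identifiers follow a row-number plus column-letter convention
#' ("01A", "02C", ...).
#'
#' @param n_rows,n_cols Grid dimensions (>= 2 each).
#' @param spacing Distance in metres between adjacent rows/columns.
#' @param missing_fraction Fraction of interior positions without a plant.
#' @param seed Integer seed for the missing-position draw.
#' @return An object of class `field_design`: a list with `n_rows`, `n_cols`,
#'   `spacing`, and a data frame `positions` with columns `plant_id`, `row`,
#'   `col` (0-based), `x`, `y` (metres), `border`, `missing`, `analysis`.
#' @examples
#' d <- make_field_design(10, 10, 0.5, missing_fraction = 0.02, seed = 1)
#' sum(d$positions$analysis)
#' @export
make_field_design <- function(n_rows, n_cols, spacing = 0.5,
                              missing_fraction = 0, seed = 1L) {
  stopifnot(n_rows >= 2, n_cols >= 2, spacing > 0,
            missing_fraction >= 0, missing_fraction < 1)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  border <- row == 0L | row == n_rows - 1L | col == 0L | col == n_cols - 1L
  plant_id <- paste0(formatC(row + 1L, width = 2, flag = "0"),
                     LETTERS[col %% 26L + 1L],
                     ifelse(col >= 26L, col %/% 26L, ""))
  missing <- rep(FALSE, length(row))
  interior <- which(!border)
  if (length(interior) == 0L)
    stop("degenerate grid: all positions are border positions")
  if (missing_fraction > 0) {
    set.seed(substream_seed(seed, "layout"))
    n_miss <- rbinom(1L, length(interior), missing_fraction)
    if (n_miss > 0)
      missing[sample(interior, n_miss)] <- TRUE
  }
  analysis <- !border & !missing
  if (sum(analysis) < 4L)
    stop("degenerate grid: fewer than 4 analysis plants")
  positions <- data.frame(
    plant_id = plant_id, row = row, col = col,
    x = col * spacing, y = row * spacing,
    border = border, missing = missing, analysis = analysis,
    stringsAsFactors = FALSE
  )
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 positions = positions),
            class = "field_design")
}

#' @export
print.field_design <- function(x, ...) {
  cat(sprintf("Field design: %d x %d grid, %.2g m spacing\n",
              x$n_rows, x$n_cols, x$spacing))
  cat(sprintf("  positions: %d (border %d, missing %d, analysis %d)\n",
              nrow(x$positions), sum(x$positions$border),
              sum(x$positions$missing), sum(x$positions$analysis)))
  invisible(x)
}

#' Coordinates of the analysis plants
#'
#' @param design A [make_field_design()] object.
#' @return Matrix with columns `x`, `y` (metres), rownames = plant ids.
#' @export
analysis_coords <- function(design) {
  stopifnot(inherits(design, "field_design"))
  p <- design$positions[design$positions$analysis, ]
  m <- cbind(x = p$x, y = p$y)
  rownames(m) <- p$plant_id
  m
}

#' Gaussian covariogram
#'
#' Builds the covariance matrix
#' \deqn{\Sigma_{ij} = \sigma^2 (\nu I_{ij} + (1-\nu) \exp(-(d_{ij}/r)^2))}
#' where `d` is the matrix of pairwise field distances, the nugget `nu` in
#' \[0, 1\] is the fraction of iid variance, and the range `r` sets how fast
#' correlation decays with distance.
#'
#' @param distances Symmetric matrix of pairwise distances, zero diagonal.
#' @param sigma2 Total variance (> 0).
#' @param nugget Nugget proportion in \[0, 1\].
#' @param range_ Range parameter in metres (> 0).
#' @return Covariance matrix of the same dimension as `distances`.
#' @export
gaussian_covariance <- function(distances, sigma2, nugget, range_) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances),
            sigma2 > 0, nugget >= 0, nugget <= 1, range_ > 0)
  if (max(abs(distances - t(distances))) > 1e-10 || any(diag(distances) != 0))
    stop("'distances' must be symmetric with zero diagonal")
  corr <- (1 - nugget) * exp(-(distances / range_)^2)
  diag(corr) <- 1 - nugget
  sigma2 * (nugget * diag(nrow(distances)) + corr)
}

#' Simulate a spatially autocorrelated latent micro-environment
#'
#' Draws one multivariate-normal realization over the analysis plants with
#' the Gaussian covariogram of [gaussian_covariance()]. This latent field is
#' the generative micro-environment that drives spatially structured gene
#' expression and phenotype variation in the synthetic trial.
#'
#' @param design A [make_field_design()] object.
#' @param sigma2 Variance of the latent field.
#' @param nugget Nugget in \[0, 1\] (1 = iid, 0 = fully spatial).
#' @param range_ Range in metres.
#' @param seed Integer seed.
#' @param n_draws Number of independent realizations (columns).
#' @return If `n_draws == 1`, a named vector over analysis plants; otherwise
#'   a plants x draws matrix.
#' @export
simulate_latent_field <- function(design, sigma2 = 1, nugget = 0.3,
                                  range_ = 1, seed = 1L, n_draws = 1L) {
  coords <- analysis_coords(design)
  d <- as.matrix(stats::dist(coords))
  sig <- gaussian_covariance(d, sigma2, nugget, range_)
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) {
    # numerically semi-definite (e.g. nugget 0, huge range): jitter the
    # diagonal minimally and report
    jit <- 1e-8 * sigma2
    warning("covariance not positive definite; adding diagonal jitter")
    ch <- chol(sig + jit * diag(nrow(sig)))
  }
  set.seed(substream_seed(seed, "latent"))
  z <- matrix(stats::rnorm(nrow(sig) * n_draws), nrow(sig), n_draws)
  out <- crossprod(ch, z)
  rownames(out) <- rownames(coords)
  if (n_draws == 1L) out[, 1L] else out
}
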