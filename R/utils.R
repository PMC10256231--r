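#' Derive a reproducible per-stage seed from a master seed
#'
#' All randomness in the simulator flows from one master seed; each stage
#' (layout, latent field, expression, phenotypes, growth) draws from its own
#' substream so that any stage can be reproduced in isolation.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed below 2^31, deterministic in `(seed, stage)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 2011L + h) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a named
#' operation so every multiple-testing family in the package goes through one
#' place.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of BH-adjusted q-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p > 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}
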