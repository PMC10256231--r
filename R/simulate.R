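#' Configuration of the synthetic field trial
#'
#' Bundles every generative parameter of the synthetic single-plant trial.
#' Defaults emulate the study conditions the package is designed for: ~62
#' analysis plants on a 10x10, 0.5 m grid; negative-binomial counts with
#' moderate overdispersion; three sequencing batches with the middle batch as
#' reference; library-size factors spread around 1; technical repeats for a
#' random 20% of plants; a spatially autocorrelated latent micro-environment
#' (nugget 0.3, range 1 m); and phenotypes driven linearly by a small set of
#' causal genes' plant effects plus spatially correlated and iid noise.
#'
#' @param n_genes Number of simulated genes.
#' @param n_causal_genes Number of genes whose plant effects drive phenotypes.
#' @param n_batches Number of sequencing batches; batch 2 is the reference
#'   when there are at least two (its effects are absorbed in the intercept).
#' @param technical_repeat_fraction Fraction of plants receiving a second,
#'   technically repeated sample (independent count draw, own batch and size
#'   factor, same plant effect).
#' @param nb_dispersion_range Range (min, max) of per-gene NB dispersions.
#' @param batch_effect_sd SD of log2-scale batch effects (reference batch 0).
#' @param size_factor_range Range of per-sample library-size factors.
#' @param latent_nugget,latent_range Nugget and range (m) of the latent field.
#' @param latent_sigma2 Variance of the latent field.
#' @param gene_loading_sd SD of per-gene loadings on the latent field.
#' @param causal_loading Absolute latent-field loading given to causal genes
#'   (so the causal signal has a known scale).
#' @param plant_effect_sd SD of the iid component of per-plant log2 effects.
#' @param base_log2_range Range of per-gene baseline log2 expression.
#' @param phenotype_effect_sizes Per-causal-gene coefficients of the
#'   continuous phenotype (recycled to `n_causal_genes`).
#' @param phenotype_spatial_coef Coefficient of the latent field in the
#'   phenotype (spatially correlated phenotype noise).
#' @param phenotype_noise_sd SD of iid phenotype noise.
#' @param ratio_beta0,ratio_beta1 Log-scale intercept and gene effect of the
#'   generated ratio phenotype (numerator ~ Normal(d exp(b0 + b1 x), sigma^2)).
#' @param ratio_noise_sd Residual SD of the ratio numerator.
#' @param seed Master seed; every stage derives its own substream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       n_causal_genes = 20L,
                       n_batches = 3L,
                       technical_repeat_fraction = 0.2,
                       nb_dispersion_range = c(0.001, 0.03),
                       batch_effect_sd = 0.3,
                       size_factor_range = c(0.7, 1.4),
                       latent_nugget = 0.3,
                       latent_range = 1.0,
                       latent_sigma2 = 1.0,
                       gene_loading_sd = 0.2,
                       causal_loading = 0.5,
                       plant_effect_sd = 0.5,
                       base_log2_range = c(5, 12),
                       phenotype_effect_sizes = 0.8,
                       phenotype_spatial_coef = 0.5,
                       phenotype_noise_sd = 1.0,
                       ratio_beta0 = 0.7,
                       ratio_beta1 = 0.3,
                       ratio_noise_sd = 2.0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_causal_genes >= 0, n_causal_genes <= n_genes,
            n_batches >= 1,
            technical_repeat_fraction >= 0, technical_repeat_fraction <= 1,
            latent_nugget >= 0, latent_nugget <= 1, latent_range > 0)
  cfg$phenotype_effect_sizes <-
    rep_len(phenotype_effect_sizes, n_causal_genes)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate per-plant expression counts for a field trial
#'
#' Generates a genes x samples count matrix under the generative model
#' \eqn{k_{ij} \sim NB(s_j \, b_i^{(batch_j)} \, 2^{\beta_{i0} + \beta_{ip_j}},
#' \alpha_i)}: per-gene baseline, count-scale batch factor, library-size
#' factor, and a per-plant log2 effect
#' \eqn{\beta_{ip} = loading_i \cdot latent_p + iid} shared by all technical
#' repeats of the same plant. Genes with zero counts in every sample are
#' removed (the only prefiltering step), with truth kept in register.
#'
#' @param design A [make_field_design()] object.
#' @param config A [sim_config()] object.
#' @param latent Per-analysis-plant latent field values
#'   (from [simulate_latent_field()]).
#' @return List with `counts` (integer matrix, genes x samples), `meta`
#'   (data frame: sample_id, plant_id, batch, row, col, x, y) and `truth`
#'   (list: latent_field, base_log2, loadings, plant_effects (genes x
#'   plants), batch_log2 (genes x batches), size_factors, dispersions,
#'   causal_gene_ids, reference_batch).
#' @export
simulate_expression <- function(design, config, latent) {
  stopifnot(inherits(design, "field_design"), inherits(config, "sim_config"))
  plants <- rownames(analysis_coords(design))
  stopifnot(!is.null(names(latent)), setequal(names(latent), plants))
  latent <- latent[plants]
  n_p <- length(plants)
  set.seed(substream_seed(config$seed, "expression"))

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  base_log2 <- stats::runif(config$n_genes, config$base_log2_range[1],
                            config$base_log2_range[2])
  causal <- sort(sample(config$n_genes, config$n_causal_genes))
  loadings <- stats::rnorm(config$n_genes, 0, config$gene_loading_sd)
  # causal genes form a coherent module reading out the same
  # micro-environmental factor: one shared loading
  loadings[causal] <- config$causal_loading
  disp <- stats::runif(config$n_genes, config$nb_dispersion_range[1],
                       config$nb_dispersion_range[2])

  plant_eff <- outer(loadings, latent) +
    matrix(stats::rnorm(config$n_genes * n_p, 0, config$plant_effect_sd),
           config$n_genes, n_p)
  dimnames(plant_eff) <- list(genes, plants)

  # samples: one per plant plus a technical repeat for a random subset
  n_rep <- round(config$technical_repeat_fraction * n_p)
  rep_plants <- if (n_rep > 0) sort(sample(n_p, n_rep)) else integer(0)
  plant_of_sample <- c(seq_len(n_p), rep_plants)
  n_s <- length(plant_of_sample)
  sample_id <- make.unique(paste0("S_", plants[plant_of_sample]), sep = "r")

  # near-equal batch split; batch 2 is the reference when it exists
  batch <- sort(rep_len(seq_len(config$n_batches), n_s))[sample(n_s)]
  ref_batch <- if (config$n_batches >= 2) 2L else 1L
  batch_log2 <- matrix(stats::rnorm(config$n_genes * config$n_batches, 0,
                                    config$batch_effect_sd),
                       config$n_genes, config$n_batches)
  batch_log2[, ref_batch] <- 0
  dimnames(batch_log2) <- list(genes, paste0("b", seq_len(config$n_batches)))

  sf <- stats::runif(n_s, config$size_factor_range[1],
                     config$size_factor_range[2])

  log2mu <- base_log2 + batch_log2[, batch, drop = FALSE] +
    plant_eff[, plant_of_sample, drop = FALSE]
  mu <- sweep(2^log2mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / disp, n_s)),
                   config$n_genes, n_s, dimnames = list(genes, sample_id))

  keep <- rowSums(counts) > 0
  pos <- design$positions[match(plants[plant_of_sample],
                                design$positions$plant_id), ]
  meta <- data.frame(sample_id = sample_id,
                     plant_id = plants[plant_of_sample],
                     batch = paste0("b", batch),
                     row = pos$row, col = pos$col, x = pos$x, y = pos$y,
                     stringsAsFactors = FALSE)
  truth <- list(latent_field = latent,
                base_log2 = base_log2[keep],
                loadings = loadings[keep],
                plant_effects = plant_eff[keep, , drop = FALSE],
                batch_log2 = batch_log2[keep, , drop = FALSE],
                size_factors = stats::setNames(sf, sample_id),
                dispersions = stats::setNames(disp[keep], genes[keep]),
                causal_gene_ids = intersect(genes[causal], genes[keep]),
                reference_batch = paste0("b", ref_batch))
  list(counts = counts[keep, , drop = FALSE], meta = meta, truth = truth)
}

#' Simulate phenotypes linked to the synthetic expression truth
#'
#' Phenotypes are driven by the *true* per-plant log2 effects of the causal
#' genes (not the observed counts), so recovery tests have a well-defined
#' target: a continuous phenotype
#' \eqn{y_p = \sum_c coef_c \beta_{c,p} + \lambda \cdot latent_p +
#' \epsilon_p}; an overdispersed count phenotype around the exponential of a
#' scaled version of the same linear predictor; and a ratio phenotype emitted
#' as a (numerator, denominator) pair with
#' \eqn{n_p \sim N(d_p \exp(\beta_0 + \beta_1 x_p), \sigma^2)} where `x` is
#' the first causal gene's plant effect.
#'
#' @param truth Truth list from [simulate_expression()].
#' @param config The [sim_config()] used.
#' @return Data frame keyed by `plant_id` with columns `yield`,
#'   `silique_count`, `ratio_num`, `ratio_den`, `ratio` plus attribute
#'   `"linear_predictor"`.
#' @export
simulate_phenotypes <- function(truth, config) {
  set.seed(substream_seed(config$seed, "phenotypes"))
  plants <- colnames(truth$plant_effects)
  n_p <- length(plants)
  causal <- truth$causal_gene_ids
  lp <- rep(0, n_p)
  if (length(causal) > 0) {
    coefs <- rep_len(config$phenotype_effect_sizes, length(causal))
    lp <- drop(coefs %*% truth$plant_effects[causal, , drop = FALSE])
  }
  lp <- lp + config$phenotype_spatial_coef * truth$latent_field
  yield <- lp + stats::rnorm(n_p, 0, config$phenotype_noise_sd)

  lp_sc <- if (stats::sd(lp) > 0) (lp - mean(lp)) / stats::sd(lp) else lp
  silique <- stats::rnbinom(n_p, mu = exp(4 + 0.4 * lp_sc), size = 20)

  x <- if (length(causal) > 0) truth$plant_effects[causal[1], ] else rep(0, n_p)
  den <- 1L + stats::rpois(n_p, 20)
  num_mean <- den * exp(config$ratio_beta0 + config$ratio_beta1 * x)
  num <- stats::rnorm(n_p, num_mean, config$ratio_noise_sd)
  num <- pmax(num, 0)

  # qualitative lesion severity (0-2): micro-environment-driven ordinal
  lesion_lat <- truth$latent_field + stats::rnorm(n_p, 0, 1)
  lesion <- findInterval(lesion_lat, stats::quantile(lesion_lat,
                                                    c(0.5, 0.85))) ## 0/1/2

  out <- data.frame(plant_id = plants, yield = yield,
                    silique_count = silique,
                    ratio_num = num, ratio_den = den, ratio = num / den,
                    lesion_score = lesion,
                    stringsAsFactors = FALSE)
  attr(out, "linear_predictor") <- stats::setNames(lp, plants)
  out
}

#' Simulate per-plant height time series
#'
#' Heights follow each plant's beta-sigmoid curve evaluated at the thermal
#' age of the measurement days, plus iid Gaussian measurement noise; the
#' curve is clamped at `hmax` from the end of growth onward.
#'
#' @param growth_params Data frame or matrix with columns `h0`, `hmax`, `tm`,
#'   `te` (GDD) and rownames = plant ids.
#' @param measurement_days Day-of-year indices of the height measurements.
#' @inheritParams gdd_transform
#' @param noise_sd Measurement noise SD in cm.
#' @param seed Integer seed.
#' @return Long data frame: plant_id, doy, age_gdd, height_cm.
#' @export
simulate_growth_series <- function(growth_params, measurement_days,
                                   temp_days, temps, t_base = 5,
                                   noise_sd = 1, seed = 1L) {
  gp <- as.data.frame(growth_params)
  stopifnot(all(c("h0", "hmax", "tm", "te") %in% colnames(gp)))
  if (any(gp$tm >= gp$te) || any(gp$h0 >= gp$hmax))
    stop("invalid growth parameters: need tm < te and h0 < hmax")
  ages <- gdd_transform(measurement_days, temp_days, temps, t_base)
  set.seed(substream_seed(seed, "growth"))
  out <- do.call(rbind, lapply(seq_len(nrow(gp)), function(i) {
    h <- beta_sigmoid_height(ages, gp$h0[i], gp$hmax[i], gp$tm[i], gp$te[i])
    data.frame(plant_id = rownames(gp)[i], doy = measurement_days,
               age_gdd = ages,
               height_cm = h + stats::rnorm(length(h), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic field trial
#'
#' Convenience wrapper running layout, latent field, expression, phenotype
#' and growth-series generation from one configuration, with all randomness
#' derived from `config$seed`.
#'
#' @inheritParams simulate_expression
#' @param n_rows,n_cols,spacing,missing_fraction Passed to
#'   [make_field_design()].
#' @return List: `design`, `latent`, `counts`, `meta`, `truth`,
#'   `phenotypes`, `growth`, `temperature` (data frame doy, temp_c).
#' @export
simulate_field_trial <- function(config = sim_config(),
                                 n_rows = 10, n_cols = 10, spacing = 0.5,
                                 missing_fraction = 0.02) {
  design <- make_field_design(n_rows, n_cols, spacing, missing_fraction,
                              seed = config$seed)
  latent <- simulate_latent_field(design, sigma2 = config$latent_sigma2,
                                  nugget = config$latent_nugget,
                                  range_ = config$latent_range,
                                  seed = config$seed)
  expr <- simulate_expression(design, config, latent)
  pheno <- simulate_phenotypes(expr$truth, config)

  # autumn-to-summer temperature course (southern-Belgium-like), days 252-530
  temp_days <- 252:530
  temps <- 12 + 8 * cos(2 * pi * (temp_days - 200) / 365)
  set.seed(substream_seed(config$seed, "weather"))
  temps <- temps + stats::rnorm(length(temps), 0, 1.5)

  plants <- pheno$plant_id
  set.seed(substream_seed(config$seed, "growth_params"))
  gp <- data.frame(h0 = stats::runif(length(plants), 8, 15),
                   hmax = stats::runif(length(plants), 120, 160),
                   tm = stats::runif(length(plants), 950, 1050),
                   te = stats::runif(length(plants), 1500, 1650),
                   row.names = plants)
  meas <- round(seq(441, 530, length.out = 14))
  growth <- simulate_growth_series(gp, meas, temp_days, temps,
                                   noise_sd = 1, seed = config$seed)
  expr$truth$growth_params <- gp

  list(design = design, latent = latent, counts = expr$counts,
       meta = expr$meta, truth = expr$truth, phenotypes = pheno,
       growth = growth,
       temperature = data.frame(doy = temp_days, temp_c = temps))
}

#' Write a synthetic trial to plain-text files
#'
#' Writes counts TSV (genes x samples), sample metadata CSV, phenotype CSV,
#' growth-series CSV, temperature CSV, layout CSV and a truth JSON into a
#' directory.
#'
#' @param trial Result of [simulate_field_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(trial$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.csv(trial$meta, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$growth, file.path(dir, "growth.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$temperature, file.path(dir, "temperature.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$design$positions, file.path(dir, "layout.csv"),
                   row.names = FALSE)
  truth <- trial$truth
  truth$plant_effects <- NULL  # large; kept in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
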