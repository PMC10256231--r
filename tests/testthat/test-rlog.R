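test_that("size factors follow the median-of-ratios definition", {
  k <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), 4, 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(estimate_size_factors(k)), c(1, 1))

  k2 <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
  expect_equal(unname(estimate_size_factors(k2)),
               c(1 / sqrt(2), sqrt(2)))

  expect_equal(unname(estimate_size_factors(matrix(5, 3, 1))), 1)
  expect_error(estimate_size_factors(matrix(0, 2, 2)), "all-zero")
})

test_that("size factors agree with the DESeq2 estimator on NB data", {
  tr <- small_trial()
  s_mine <- estimate_size_factors(tr$counts)
  s_ref <- DESeq2::estimateSizeFactorsForMatrix(tr$counts)
  # both use median-of-ratios; scales differ (geometric-mean-1 here), so
  # compare after rescaling
  s_ref <- s_ref / exp(mean(log(s_ref)))
  expect_equal(unname(s_mine), unname(s_ref), tolerance = 1e-10)
})

test_that("dispersion estimation recovers NB alpha and floors degenerate genes", {
  set.seed(21)
  n <- 500
  k <- rbind(nb = rnbinom(n, mu = 100, size = 2),     # alpha = 0.5
             pois = rpois(n, 100),
             const = rep(7L, n))
  a <- estimate_dispersions(k, size_factors = rep(1, n))
  expect_equal(unname(a["nb"]), 0.5, tolerance = 0.1)
  expect_lt(a["pois"], 0.02)
  expect_equal(unname(a["const"]), 1e-8)
  a_mle <- estimate_dispersions(k, size_factors = rep(1, n),
                                refine_mle = TRUE)
  expect_equal(unname(a_mle["nb"]), 0.5, tolerance = 0.1)
})

test_that("rlog collapses to the intercept when there is nothing to explain", {
  n <- 12
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     plant_id = paste0("p", 1:n),
                     batch = "b1", stringsAsFactors = FALSE)
  k <- matrix(64L, 3, n, dimnames = list(paste0("g", 1:3), meta$sample_id))
  fit <- rlog_fit(k, meta, size_factors = setNames(rep(1, n),
                                                   meta$sample_id))
  expect_equal(unname(fit$beta0), rep(log2(64), 3), tolerance = 1e-5)
  expect_lt(max(abs(fit$plant_effects)), 1e-4)
  # constant gene: constant rlog row
  expect_lt(diff(range(rlog_matrix(fit)[1, ])), 1e-4)
})

test_that("prior variance limits behave as infinite and zero shrinkage", {
  # one sample per plant, one batch: prior -> Inf approaches the saturated
  # per-sample NB MLE, log2(k/s); prior -> 0 collapses plant effects
  set.seed(31)
  n <- 20
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     plant_id = paste0("p", 1:n), batch = "b1",
                     stringsAsFactors = FALSE)
  k <- matrix(rnbinom(5 * n, mu = 300, size = 10), 5, n,
              dimnames = list(paste0("g", 1:5), meta$sample_id))
  s <- setNames(rep(1, n), meta$sample_id)

  f_inf <- rlog_fit(k, meta, size_factors = s, prior_var = 1e8)
  rl <- rlog_matrix(f_inf)[, meta$plant_id]   # align plant to sample order
  expect_equal(max(abs(rl - log2(k))), 0, tolerance = 1e-3)

  f0 <- rlog_fit(k, meta, size_factors = s, prior_var = 0)
  expect_equal(max(abs(f0$plant_effects)), 0)
  expect_equal(unname(rlog_matrix(f0)[, 1]), unname(f0$beta0))
})

test_that("shrinkage is monotone relative to the near-flat-prior fit", {
  # single batch, one sample per plant: the penalized fit contracts every
  # plant effect towards zero (pointwise up to refit tolerance)
  set.seed(50)
  n <- 24
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     plant_id = paste0("p", 1:n), batch = "b1",
                     stringsAsFactors = FALSE)
  k <- matrix(rnbinom(30 * n, mu = rep(2^runif(30, 5, 10), n), size = 50),
              30, n, dimnames = list(paste0("g", 1:30), meta$sample_id))
  s <- setNames(rep(1, n), meta$sample_id)
  fit <- rlog_fit(k, meta, size_factors = s, prior_var = 0.05)
  flat <- rlog_fit(k, meta, size_factors = s,
                   dispersions = fit$dispersions, prior_var = 1e8)
  expect_true(all(abs(fit$plant_effects) <=
                    abs(flat$plant_effects) + 0.01))

  # with co-estimated batch coefficients the contraction holds in
  # aggregate: overall magnitude shrinks and pointwise violations are rare
  tr <- small_trial()
  kb <- tr$counts[1:25, , drop = FALSE]
  fb <- rlog_fit(kb, tr$meta)
  flb <- rlog_fit(kb, tr$meta, size_factors = fb$size_factors,
                  dispersions = fb$dispersions, prior_var = 1e8,
                  ref_batch = fb$ref_batch)
  expect_lt(mean(abs(fb$plant_effects)), mean(abs(flb$plant_effects)))
  expect_gt(mean(abs(fb$plant_effects) <= abs(flb$plant_effects) + 0.02),
            0.95)
})

test_that("rescaling one batch's counts leaves the rlog matrix unchanged", {
  tr <- small_trial()
  k <- tr$counts[1:20, , drop = FALSE]
  fit <- rlog_fit(k, tr$meta, ref_batch = "b2")
  k2 <- k
  idx <- tr$meta$batch == "b3"
  k2[, idx] <- k2[, idx] * 4L
  fit2 <- rlog_fit(k2, tr$meta, size_factors = fit$size_factors,
                   dispersions = fit$dispersions, prior_var = fit$prior_var,
                   ref_batch = "b2")
  expect_equal(rlog_matrix(fit2), rlog_matrix(fit), tolerance = 0.02)
  # the scaled batch's coefficient absorbs the factor of 4 (2 log2 units)
  expect_equal(mean(fit2$batch_log2[, "b3"] - fit$batch_log2[, "b3"]), 2,
               tolerance = 0.05)
})

test_that("rlog unites technical repeats and recovers true plant effects", {
  tr <- small_trial(n_genes = 80, seed = 42)
  fit <- rlog_fit(tr$counts, tr$meta)
  rl <- rlog_matrix(fit)
  # one column per plant, not per sample
  expect_equal(ncol(rl), length(unique(tr$meta$plant_id)))
  expect_equal(rl, fit$beta0 + fit$plant_effects)
  # permuting sample order leaves the result unchanged
  perm <- sample(ncol(tr$counts))
  fit_p <- rlog_fit(tr$counts[, perm], tr$meta[perm, ],
                    size_factors = fit$size_factors[perm],
                    dispersions = fit$dispersions,
                    prior_var = fit$prior_var, ref_batch = fit$ref_batch)
  expect_equal(rlog_matrix(fit_p)[, colnames(rl)], rl, tolerance = 1e-6)
  # recovery of the generative plant effects
  truth <- tr$truth$plant_effects[rownames(rl), colnames(rl)]
  norm <- batch_normalized_counts(tr$counts, fit)
  eligible <- rowMeans(norm) >= 20
  cors <- vapply(which(eligible), function(i) cor(rl[i, ], truth[i, ]),
                 numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("batch-normalized counts divide out batch factors and average repeats", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     plant_id = c("p1", "p1", "p2"),
                     batch = c("b1", "b2", "b1"), stringsAsFactors = FALSE)
  fit <- structure(list(
    beta0 = c(g1 = 3), batch_log2 = matrix(c(1, 0), 1, 2,
                                           dimnames = list("g1", c("b1", "b2"))),
    plant_effects = matrix(0, 1, 2, dimnames = list("g1", c("p1", "p2"))),
    size_factors = setNames(c(1, 1, 2), meta$sample_id),
    dispersions = c(g1 = 0.01), meta = meta, ref_batch = "b2",
    prior_var = 1, converged = TRUE, fallback = FALSE),
    class = "rlog_fit")
  k <- matrix(c(20L, 14L, 40L), 1, 3,
              dimnames = list("g1", meta$sample_id))
  # s1: 20/(2^1 * 1) = 10; s2: 14/1 = 14 -> plant p1 average 12
  # s3: 40/(2^1 * 2) = 10
  out <- batch_normalized_counts(k, fit)
  expect_equal(unname(out[1, ]), c(12, 10))
})
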