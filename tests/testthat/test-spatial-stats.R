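test_that("queen weights match the adjacency census on full grids", {
  # 2x2: all four cells mutually adjacent -> 12 ordered connected pairs
  d4 <- make_field_design(4, 4, 0.5, 0, seed = 1)
  w4 <- build_spatial_weights(d4, "queen")
  expect_equal(w4$w, 12)
  expect_true(isSymmetric(w4$C))
  expect_equal(unname(diag(w4$C)), rep(0, 4))

  # 3x3 interior of a 5x5: corners 3, edges 5, center 8 -> w = 40
  d5 <- make_field_design(5, 5, 0.5, 0, seed = 1)
  w5 <- build_spatial_weights(d5, "queen")
  deg <- rowSums(w5$C)
  expect_equal(sort(unname(deg)), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
  expect_equal(w5$w, 40)

  # degree census on a large full grid: 4 corners x3, edge cells x5,
  # interior x8
  d10 <- full_design(12, 12)
  w10 <- build_spatial_weights(d10, "queen")
  nr <- 10; nc <- 10
  expect_equal(w10$w, 4 * 3 + (2 * (nr - 2) + 2 * (nc - 2)) * 5 +
                 (nr - 2) * (nc - 2) * 8)
})

test_that("inverse-distance weights are reciprocal distances", {
  d <- make_field_design(4, 4, 0.5, 0, seed = 1)
  w <- build_spatial_weights(d, "inverse_distance")
  co <- analysis_coords(d)
  dm <- as.matrix(dist(co))
  expect_equal(w$C[1, 2], 1 / dm[1, 2])
  expect_equal(max(abs(w$C - t(w$C))), 0)
  # adjacent plants 0.5 m apart -> weight 2
  expect_true(any(abs(w$C - 2) < 1e-12))
})

test_that("Moran's I equals the brute-force double sum", {
  d <- make_field_design(4, 4, 0.5, 0, seed = 1)
  w <- build_spatial_weights(d, "queen")
  x <- c(1, -1, -1, 1)
  names(x) <- w$plants
  expect_equal(morans_i(x, w), -1 / 3)
  expect_equal(morans_i(x, w), moran_brute(unname(x), w$C))

  d6 <- full_design(6, 6)
  w6 <- build_spatial_weights(d6, "queen")
  set.seed(8)
  y <- rnorm(16)
  names(y) <- w6$plants
  expect_equal(morans_i(y, w6), moran_brute(unname(y), w6$C))

  expect_error(morans_i(setNames(rep(1, 16), w6$plants), w6),
               "zero variance")
})

test_that("Moran's I and its permutation p are affine-invariant", {
  d <- full_design(7, 7)
  w <- build_spatial_weights(d, "queen")
  set.seed(12)
  x <- rnorm(25)
  names(x) <- w$plants
  expect_equal(morans_i(3 * x - 10, w), morans_i(x, w))
  p1 <- moran_permutation_test(x, w, 499, seed = 5)$p_perm
  p2 <- moran_permutation_test(-2 * x + 1, w, 499, seed = 5)$p_perm
  # -2x reverses the tail; same-scale affine with positive slope matches
  p3 <- moran_permutation_test(5 * x + 2, w, 499, seed = 5)$p_perm
  expect_equal(p1, p3)
  expect_true(is.numeric(p2))
})

test_that("permutation pseudo-p matches exhaustive enumeration at n = 4", {
  # non-complete graph on 4 plants so I varies across permutations:
  # take a 1x4 line of interior cells from a 3x6 grid
  d <- make_field_design(3, 6, 0.5, 0, seed = 1)
  w <- build_spatial_weights(d, "queen")
  expect_length(w$plants, 4)
  x <- c(2.0, 0.5, -1.0, 0.25)
  names(x) <- w$plants
  i_obs <- morans_i(x, w)
  # enumeration oracle over all 24 orderings
  perms <- matrix(unlist(combinat_perms <- {
    p <- list(); idx <- 1:4
    rec <- function(pre, rest) {
      if (!length(rest)) { p[[length(p) + 1]] <<- pre; return() }
      for (r in rest) rec(c(pre, r), setdiff(rest, r))
    }
    rec(integer(0), idx); p
  }), ncol = 4, byrow = TRUE)
  i_all <- apply(perms, 1, function(o) moran_brute(unname(x)[o], w$C))
  p_exact <- mean(i_all >= i_obs - 1e-12)
  pt <- moran_permutation_test(x, w, n_perm = 20000, seed = 2)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(pt$p_perm - p_exact), 2 * mc_se + 2 / 20001)
})

test_that("parametric test matches the closed form and the ape oracle", {
  d <- full_design(8, 8)
  w <- build_spatial_weights(d, "queen")
  set.seed(3)
  x <- rnorm(36)
  names(x) <- w$plants
  res <- moran_parametric_test(x, w)
  expect_equal(res$expected, -1 / 35)
  # exact oracle: S1, S2 and the normality variance by explicit loops
  C <- w$C
  n <- length(x)
  s1 <- s2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) s1 <- s1 + 0.5 * (C[i, j] + C[j, i])^2
    s2 <- s2 + (sum(C[i, ]) + sum(C[, i]))^2
  }
  v_ref <- (n^2 * s1 - n * s2 + 3 * w$w^2) / ((n^2 - 1) * w$w^2) -
    (1 / (n - 1))^2
  expect_equal(res$variance, v_ref, tolerance = 1e-12)

  # ape uses the randomization (kurtosis-corrected) variance; the two
  # nulls agree closely for near-normal data. Feed ape a pre-row-
  # standardized matrix so its internal normalization is a no-op.
  Crs <- w$C / rowSums(w$C)
  wrs <- structure(list(C = Crs, w = sum(Crs), mode = "queen",
                        plants = w$plants), class = "spatial_weights")
  mine <- moran_parametric_test(x, wrs)
  ref <- ape::Moran.I(unname(x), Crs)
  expect_equal(mine$I, ref$observed, tolerance = 1e-12)
  expect_equal(sqrt(mine$variance), ref$sd, tolerance = 0.05)
  expect_equal(mine$p_param, ref$p.value, tolerance = 0.05)

  # complete graph: I is degenerate at E[I], two-sided p = 1
  d2 <- make_field_design(4, 4, 0.5, 0, seed = 1)
  w2 <- build_spatial_weights(d2, "queen")
  x2 <- setNames(c(1, -1, -1, 1), w2$plants)
  deg <- moran_parametric_test(x2, w2)
  expect_equal(deg$p_param, 1)

  # E[I] closed form at n = 10
  d10 <- make_field_design(4, 7, 0.5, 0, seed = 1)
  w10 <- build_spatial_weights(d10, "queen")
  set.seed(4)
  x10 <- setNames(rnorm(10), w10$plants)
  expect_equal(moran_parametric_test(x10, w10)$expected, -1 / 9)
})

test_that("parametric and permutation p agree in rank order on smooth fields", {
  d <- full_design(8, 8)
  w <- build_spatial_weights(d, "queen")
  Z <- simulate_latent_field(d, 1, nugget = 0.4, range_ = 1.2, seed = 6,
                             n_draws = 50)
  pp <- pq <- numeric(50)
  for (j in 1:50) {
    x <- Z[, j]
    pp[j] <- moran_permutation_test(x, w, 4999, seed = j)$p_perm
    pq[j] <- moran_parametric_test(x, w)$p_param
  }
  expect_gte(cor(rank(pp), rank(pq), method = "spearman"), 0.9)
})

test_that("moran_screen drops missing plants per feature and BH-adjusts", {
  d <- full_design(6, 6)
  w <- build_spatial_weights(d, "queen")
  set.seed(10)
  X <- matrix(rnorm(5 * 16), 5, 16,
              dimnames = list(paste0("f", 1:5), w$plants))
  X[3, 1:2] <- NA
  out <- moran_screen(X, d, n_perm = 199, seed = 1)
  expect_equal(nrow(out), 5)
  expect_true(all(out$q_perm >= out$p_perm - 1e-12))
  expect_false(any(is.na(out$I)))
  # reduced-set result equals screening the complete cases directly
  ok <- is.finite(X[3, ])
  w_red <- build_spatial_weights(d, "queen", plants = colnames(X)[ok])
  expect_equal(out$I[3], morans_i(X[3, ok], w_red))
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
})
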