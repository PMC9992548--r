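test_that("edge-free configurations imply an empty partial-correlation structure", {
  tr <- generate_truth(synthetic_config(
    within_edge_weight = 0, bridge_edges = NULL, cross_lagged = NULL,
    autoregressive = 0))
  expect_equal(tr$pcor_T1, matrix(0, 17, 17,
                                  dimnames = dimnames(tr$pcor_T1)))
  # two 2-item communities: exactly one within edge each, at the set weight
  tr2 <- generate_truth(synthetic_config(
    community_sizes = c(2L, 2L), within_edge_weight = 0.3,
    bridge_edges = NULL, cross_lagged = NULL, autoregressive = 0,
    reverse_coded = rep(FALSE, 4)))
  up <- tr2$pcor_T1[upper.tri(tr2$pcor_T1)]
  expect_identical(sum(up != 0), 2L)
  expect_equal(up[up != 0], c(0.3, 0.3))
})

test_that("default precision matrix is positive definite (frozen eigenvalue)", {
  tr <- generate_truth(synthetic_config())
  ev_min <- min(eigen(tr$precision_T1, symmetric = TRUE,
                      only.values = TRUE)$values)
  expect_gt(ev_min, 0)
  # regression value recorded from the eigendecomposition of the default
  expect_equal(ev_min, 0.4911229721, tolerance = 1e-8)
  # an overloaded configuration is rejected with the offending eigenvalue
  expect_error(synthetic_config(within_edge_weight = 0.6),
               "smallest eigenvalue")
})

test_that("stored precision and partial correlations satisfy the GGM identity", {
  tr <- generate_truth(synthetic_config())
  K <- tr$precision_T1
  d <- sqrt(diag(K))
  expected <- -K / tcrossprod(d)
  diag(expected) <- 0
  expect_equal(tr$pcor_T1, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$pcor_T1, t(tr$pcor_T1))
  expect_true(all(diag(tr$pcor_T1) == 0))
  expect_true(all(abs(tr$pcor_T1) < 1))
  # thresholds strictly increasing per item
  expect_true(all(apply(tr$thresholds, 1, function(x) all(diff(x) > 0))))
  # precision is the exact inverse of the latent correlation matrix
  expect_equal(K %*% tr$sigma_T1, diag(17), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("panel simulation is deterministic and validates its inputs", {
  tr <- generate_truth(synthetic_config())
  p1 <- simulate_panel(tr, 50, seed = 7)
  p2 <- simulate_panel(tr, 50, seed = 7)
  expect_identical(p1$T1$responses, p2$T1$responses)
  expect_identical(p1$T2$responses, p2$T2$responses)
  expect_false(identical(p1$T1$responses,
                         simulate_panel(tr, 50, seed = 8)$T1$responses))
  expect_error(simulate_panel(tr, 5), "at least 10")
  expect_identical(nrow(p1$T1$responses), nrow(p1$T2$responses))
  expect_true(all(p1$T1$responses %in% 1:4))
})

test_that("a dependence-free truth produces near-zero sample correlations", {
  tr <- generate_truth(synthetic_config(
    within_edge_weight = 0, bridge_edges = NULL, cross_lagged = NULL,
    autoregressive = 0))
  pair <- simulate_panel(tr, 1000, seed = 11)
  R <- cor(pair$T1$responses)
  expect_lt(max(abs(R[upper.tri(R)])), 0.11)
})

test_that("category frequencies and latent covariance match the configured truth", {
  tr <- generate_truth(synthetic_config())
  n <- 1e5
  pair <- simulate_panel(tr, n, seed = 3)
  # orthant probabilities implied by the thresholds
  for (j in c(1, 8, 15)) {   # one item per community
    cuts <- c(-Inf, tr$thresholds[j, ], Inf)
    expected <- diff(pnorm(cuts))
    observed <- tabulate(pair$T1$responses[, j], 4) / n
    expect_true(all(abs(observed - expected) < 0.01))
  }
  # the sampling error of a 17 x 17 covariance keeps the raw Frobenius
  # distance near 0.05 at this n; require relative closeness plus an
  # explicit decrease with sample size
  z <- attr(pair, "latent")$T1
  err_big <- sqrt(sum((cov(z) - tr$sigma_T1)^2))
  expect_lt(err_big / sqrt(sum(tr$sigma_T1^2)), 0.05)
  z_small <- attr(simulate_panel(tr, 2000, seed = 3), "latent")$T1
  expect_lt(err_big, sqrt(sum((cov(z_small) - tr$sigma_T1)^2)))
  # unit-variance scaling of the T2 latents
  z2 <- attr(pair, "latent")$T2
  expect_true(all(abs(apply(z2, 2, var) - 1) < 0.05))
})

test_that("a single cross-lagged path is recovered against a Monte-Carlo oracle", {
  cross <- data.frame(from = "D6", to = "A1", weight = 0.4)
  tr <- generate_truth(synthetic_config(
    within_edge_weight = 0, bridge_edges = NULL, cross_lagged = cross,
    autoregressive = 0))
  # attenuated slope oracle: discretize the outcome at n = 1e6 and
  # regress the ordinal response on the standardized latent predictor
  set.seed(99)
  n_mc <- 1e6
  d6 <- rnorm(n_mc)
  a1_lat <- 0.4 * d6 + sqrt(1 - 0.16) * rnorm(n_mc)
  a1_obs <- findInterval(a1_lat, tr$thresholds["A1", ]) + 1L
  slope_mc <- cov(a1_obs, d6) / var(d6)

  pair <- simulate_panel(tr, 4000, seed = 17)
  z1 <- attr(pair, "latent")$T1
  y <- pair$T2$responses[, "A1"]
  x <- as.numeric(scale(z1[, "D6"]))
  slope_hat <- cov(y, x) / var(x)
  expect_lt(abs(slope_hat - slope_mc), 0.08)
})

test_that("panel CSV and truth JSON round-trip without loss", {
  tr <- generate_truth(synthetic_config())
  pair <- simulate_panel(tr, 60, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pair, f)
  back <- read_panel_csv(f)
  expect_identical(back$T1$responses, pair$T1$responses)
  expect_identical(back$T2$responses, pair$T2$responses)
  expect_identical(back$T1$community_labels, pair$T1$community_labels)
  jf <- tempfile(fileext = ".json")
  write_truth_json(tr, jf)
  obj <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(matrix(unlist(obj$pcor_T1), 17, 17, byrow = FALSE),
               unname(tr$pcor_T1), tolerance = 1e-12)
})
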