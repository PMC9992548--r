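make_panel <- function(m, comm = NULL, labels = colnames(m)) {
  ordinal_panel(m, labels, comm)
}

test_that("descriptives reproduce hand-computed moments and item-rest correlations", {
  m <- cbind(a = c(1L, 1L, 2L), b = c(2L, 1L, 2L))
  d <- compute_descriptives(make_panel(m))
  expect_equal(d$mean[1], 4 / 3)
  expect_equal(d$sd[1], sqrt(1 / 3), tolerance = 1e-12)   # 0.577 with n-1
  # symmetric column has zero moment skewness
  m2 <- cbind(a = c(1L, 2L, 2L, 3L), b = c(1L, 1L, 2L, 2L))
  d2 <- compute_descriptives(make_panel(m2))
  expect_equal(d2$skewness[1], 0)
  # item-rest correlation is the correlation with the rest-sum of its scale
  expect_equal(d2$item_rest[1], cor(m2[, 1], m2[, 2]))
  # single-item scale rejected
  comm <- c(a = "x", b = "y")
  expect_error(compute_descriptives(make_panel(m2, comm)), "single-item")
})

test_that("synthetic panel skewness matches the moment-formula oracle with expected signs", {
  tr <- generate_truth(synthetic_config())
  pair <- simulate_panel(tr, 5000, seed = 21)
  d <- compute_descriptives(pair$T1)
  x <- pair$T1$responses
  oracle <- apply(x, 2, function(col) {
    n <- length(col); mu <- mean(col)
    m2 <- sum((col - mu)^2) / n
    (sum((col - mu)^3) / n) / m2^1.5
  })
  expect_equal(d$skewness, unname(oracle), tolerance = 1e-12)
  expect_true(all(d$skewness[d$community == "anxiety"] > 0))
  expect_true(all(d$skewness[d$community == "depression"] < 0))
  # excess-kurtosis convention: a symmetric binary split would be negative
  oracle_k <- apply(x, 2, function(col) {
    n <- length(col); mu <- mean(col)
    m2 <- sum((col - mu)^2) / n
    (sum((col - mu)^4) / n) / m2^2 - 3
  })
  expect_equal(d$kurtosis, unname(oracle_k), tolerance = 1e-12)
})

test_that("goldbricker flags duplicated items and matches the brute-force screen", {
  tr <- generate_truth(synthetic_config())
  pair <- simulate_panel(tr, 1500, seed = 31)
  resp <- pair$T1$responses
  resp[, "A2"] <- resp[, "A1"]
  pan <- ordinal_panel(resp, pair$T1$item_labels, pair$T1$community_labels)
  gb <- goldbricker(pan)
  row <- gb[gb$item_i == "A1" & gb$item_j == "A2", ]
  expect_identical(nrow(row), 1L)
  expect_true(row$redundant)
  expect_equal(row$prop_significant, 0)
  # weakly related items never reach the correlation gate
  trn <- generate_truth(synthetic_config(
    within_edge_weight = 0, bridge_edges = NULL, cross_lagged = NULL,
    autoregressive = 0))
  gb0 <- goldbricker(simulate_panel(trn, 500, seed = 8)$T1)
  expect_identical(nrow(gb0), 0L)
  # printed 4-variable correlation fixture vs nested-loop oracle
  R <- matrix(c(1, 0.62, 0.55, 0.30,
                0.62, 1, 0.58, 0.28,
                0.55, 0.58, 1, 0.12,
                0.30, 0.28, 0.12, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  got <- goldbricker(R, n = 400, cor_min = 0.5)
  oracle <- brute_goldbricker_props(R, 400, alpha = 0.01, cor_min = 0.5)
  expect_identical(nrow(got), length(oracle))
  for (r in seq_len(nrow(got))) {
    key <- paste(match(got$item_i[r], letters), match(got$item_j[r], letters))
    expect_equal(got$prop_significant[r], oracle[[key]])
  }
  # symmetric in the pair: same report when columns are reordered
  R2 <- R[4:1, 4:1]
  got2 <- goldbricker(R2, n = 400, cor_min = 0.5)
  key1 <- with(got, paste(pmin(item_i, item_j), pmax(item_i, item_j)))
  key2 <- with(got2, paste(pmin(item_i, item_j), pmax(item_i, item_j)))
  expect_setequal(key1, key2)
})

test_that("nonparanormal transform is a standardized, monotone, idempotent rank map", {
  x <- matrix(1:50, ncol = 1)
  z <- nonparanormal_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(z), -rev(as.numeric(z)), tolerance = 1e-10)
  expect_true(all(diff(as.numeric(z)) > 0))

  set.seed(5)
  xo <- matrix(sample(1:4, 600, replace = TRUE), ncol = 3)
  z1 <- nonparanormal_transform(xo)
  z2 <- nonparanormal_transform(z1)
  expect_lt(max(abs(z2 - z1)), 1e-8)
  # ties share scores, distinct values keep their order
  for (j in 1:3) {
    o <- order(xo[, j])
    expect_true(all(diff(z1[o, j]) >= 0))
    expect_true(all((diff(xo[o, j]) == 0) == (diff(z1[o, j]) == 0)))
  }
  # transformed uniform draws are nearly symmetric
  set.seed(6)
  u <- matrix(runif(100), ncol = 1)
  zu <- nonparanormal_transform(u)
  sk <- sum((zu - mean(zu))^3) / 100 / (sum((zu - mean(zu))^2) / 100)^1.5
  expect_lt(abs(sk), 0.15)
  expect_error(nonparanormal_transform(matrix(rep(2, 20), ncol = 1)),
               "zero-variance")
})
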