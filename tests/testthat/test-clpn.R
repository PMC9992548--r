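test_that("an exactly copied item yields a pure autoregressive path", {
  tr <- small_clpn_truth()
  pair <- simulate_panel(tr, 2000, seed = 1)
  pair$T2$responses[, 1] <- pair$T1$responses[, 1]
  m <- fit_clpn(pair, seed = 2)
  expect_gte(m$beta[1, 1], 0.99)
  expect_true(all(m$beta[-1, 1] == 0))
  expect_equal(unname(m$in_prediction[1]), 1, tolerance = 1e-6)
})

test_that("incoming paths of a dependence-free item stay small", {
  # item 2 has no autoregression and no incoming cross path; the
  # minimum-CV rule may keep a few spurious paths, but they remain tiny
  tr <- small_clpn_truth()
  spurious <- sapply(1:10, function(s) {
    pair <- simulate_panel(tr, 2000, seed = 100 + s)
    m <- fit_clpn(pair, seed = s)
    max(abs(m$beta[, 2]))
  })
  expect_lt(max(spurious), 0.08)
  expect_gte(mean(spurious == 0), 0.2)
})

test_that("out-prediction is the brute-force sum of squared outgoing paths", {
  set.seed(3)
  beta <- matrix(0, 6, 6, dimnames = rep(list(paste0("v", 1:6)), 2))
  beta[cbind(sample(6, 8, TRUE), sample(6, 8, TRUE))] <-
    runif(8, -0.5, 0.5)
  fake <- structure(list(beta = beta, item_labels = rownames(beta)),
                    class = "clpn_model")
  out <- out_prediction(fake)
  oracle <- vapply(1:6, function(s) {
    tot <- 0
    for (t in 1:6) if (t != s) tot <- tot + beta[s, t]^2
    tot
  }, numeric(1))
  expect_equal(unname(out), oracle)
  # hand case: betas {0.3, -0.4} -> 0.25
  b2 <- matrix(0, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  b2[1, 2] <- 0.3; b2[1, 3] <- -0.4
  fake2 <- structure(list(beta = b2, item_labels = letters[1:3]),
                     class = "clpn_model")
  expect_equal(unname(out_prediction(fake2)[["a"]]), 0.25)
  # autoregressive paths enter only on request
  b2[1, 1] <- 0.5
  fake2$beta <- b2
  expect_equal(unname(out_prediction(fake2)[["a"]]), 0.25)
  expect_equal(unname(out_prediction(fake2, include_auto = TRUE)[["a"]]),
               0.5)
})

test_that("in-prediction is zero for empty models and node-label invariant", {
  tr <- small_clpn_truth(autoregressive = rep(0, 4))
  pair <- simulate_panel(tr, 500, seed = 6)
  m <- fit_clpn(pair, seed = 7)
  m0 <- m
  m0$beta <- m$beta * 0
  expect_true(all(in_prediction(m0) == 0))
  # relabeling other nodes does not change a node's in-prediction
  m1 <- m
  swap <- c(1, 3, 2, 4)
  m1$beta <- m$beta[swap, , drop = FALSE]
  m1$scores$T1 <- m$scores$T1[, swap]
  expect_equal(in_prediction(m1), in_prediction(m))
})

test_that("the selected lasso solutions match a coordinate-descent oracle", {
  tr <- generate_truth(synthetic_config(
    community_sizes = c(3L, 2L), within_edge_weight = 0.2,
    bridge_edges = NULL,
    cross_lagged = data.frame(from = "A2", to = "A1", weight = 0.3),
    autoregressive = 0.3, threshold_skew = 0.4,
    reverse_coded = rep(FALSE, 5)))
  pair <- simulate_panel(tr, 800, seed = 8)
  m <- fit_clpn(pair, seed = 9)
  x <- m$scores$T1
  for (t in 1:5) {
    oracle <- cd_lasso(x, m$scores$T2[, t], m$lambda[t])
    expect_lt(max(abs(m$beta[, t] - oracle)), 1e-8)
  }
  # retained zeros are exact, not numerically small
  expect_true(all(m$beta[m$beta != 0] != 0))
  expect_true(any(m$beta == 0))
})

test_that("true cross-lagged paths are recovered near the OLS-on-support oracle", {
  cl <- data.frame(from = c("L3", "L2", "D6"), to = c("A1", "A1", "L2"),
                   weight = c(0.3, 0.3, 0.4))
  tr <- generate_truth(synthetic_config(cross_lagged = cl,
                                        autoregressive = 0.4))
  sup <- tr$beta_full != 0
  for (s in 1:3) {
    pair <- simulate_panel(tr, 4000, seed = 40 + s)
    m <- fit_clpn(pair, seed = s)
    expect_true(all(m$beta[sup] != 0))
    expect_true(all(sign(m$beta[sup]) == sign(tr$beta_full[sup])))
    # unpenalized least squares on the true support, same transformed data
    for (t in which(colSums(sup) > 0)) {
      idx <- which(sup[, t])
      ols <- qr.coef(qr(m$scores$T1[, idx, drop = FALSE]),
                     m$scores$T2[, t])
      expect_lt(max(abs(m$beta[idx, t] - ols)), 0.1)
    }
  }
})

test_that("path-model fit indices behave at their boundary conventions", {
  # model reproducing its own implied covariance fits perfectly
  tr <- small_clpn_truth()
  pair <- simulate_panel(tr, 1000, seed = 12)
  m <- fit_clpn(pair, seed = 13)
  fi <- path_model_fit(m)
  fi2 <- path_model_fit(m$beta != 0, S = fi$implied, n = 1000)
  expect_lt(fi2$SRMR, 1e-10)
  expect_lt(abs(fi2$chi_square), 1e-6)
  expect_equal(fi2$CFI, 1)
  # independence data: baseline chi-square below its df forces CFI = 1
  sup <- matrix(FALSE, 4, 4); sup[1, 1] <- TRUE
  fi3 <- path_model_fit(sup, S = diag(8), n = 200)
  expect_equal(fi3$CFI, 1)
  expect_equal(fi3$SRMR, 0)
  expect_true(fi3$TLI <= 1)
  expect_error(path_model_fit(matrix(FALSE, 4, 4), S = diag(8), n = 200),
               "no paths")
})
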