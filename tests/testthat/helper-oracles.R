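# Independent reference implementations used to cross-check the package:
# every oracle here is written against the definition, not against the
# package's code path.

# double-loop expected influence
brute_ei <- function(w, steps = 1) {
  p <- ncol(w)
  ei1 <- numeric(p)
  for (i in 1:p) for (j in 1:p) ei1[i] <- ei1[i] + w[i, j]
  if (steps == 1) return(ei1)
  ei2 <- ei1
  for (i in 1:p) for (j in 1:p) ei2[i] <- ei2[i] + w[i, j] * ei1[j]
  ei2
}

# double-loop bridge expected influence
brute_bei <- function(w, memb, steps = 1) {
  p <- ncol(w)
  b1 <- numeric(p)
  for (i in 1:p) for (j in 1:p)
    if (memb[i] != memb[j]) b1[i] <- b1[i] + w[i, j]
  if (steps == 1) return(b1)
  b2 <- b1
  for (i in 1:p) for (j in 1:p)
    if (memb[i] != memb[j]) b2[i] <- b2[i] + w[i, j] * b1[j]
  b2
}

# clique percolation by exhaustive subset enumeration and repeated merging;
# returns communities as a sorted list of sorted node-index vectors
brute_cpm <- function(w, k, I) {
  p <- ncol(w)
  subs <- combn(p, k)
  keep <- list()
  for (ci in seq_len(ncol(subs))) {
    nodes <- subs[, ci]
    sub <- w[nodes, nodes]
    vals <- sub[upper.tri(sub)]
    if (all(vals != 0) && exp(mean(log(abs(vals)))) >= I)
      keep[[length(keep) + 1L]] <- nodes
  }
  if (length(keep) == 0) return(list())
  comp <- seq_along(keep)
  repeat {
    changed <- FALSE
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      if (comp[a] != comp[b] &&
          length(intersect(keep[[a]], keep[[b]])) == k - 1) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp),
                function(cc) sort(unique(unlist(keep[comp == cc]))))
  cpm_sort(out)
}

cpm_sort <- function(sets) {
  key <- vapply(sets, function(cc) paste(sprintf("%03d", cc),
                                         collapse = ","), character(1))
  sets[order(key)]
}

# package communities as sorted index sets, comparable to brute_cpm output
cpm_canon <- function(oc, net) {
  cpm_sort(lapply(oc$communities,
                  function(cc) sort(match(cc, net$node_labels))))
}

# proximal-gradient (ISTA) solver for the penalized precision objective,
# with backtracking to stay positive definite
ista_glasso <- function(S, lambda, iters = 100000, tol = 1e-13) {
  K <- diag(1 / diag(S))
  neg_obj <- function(K) -glasso_objective(K, S, lambda)
  t_step <- 0.1
  last <- neg_obj(K)
  for (it in seq_len(iters)) {
    G <- -solve(K) + S
    repeat {
      Kn <- K - t_step * G
      off <- Kn - diag(diag(Kn))
      off <- sign(off) * pmax(abs(off) - t_step * lambda, 0)
      Kn <- off + diag(diag(Kn))
      ok <- !inherits(tryCatch(chol(Kn), error = function(e) e), "error")
      if (ok) {
        fn <- neg_obj(Kn)
        if (fn <= last + 1e-12) break
      }
      t_step <- t_step / 2
    }
    if (abs(last - fn) < tol && it > 100) return(Kn)
    K <- Kn
    last <- fn
    t_step <- min(t_step * 1.05, 1)
  }
  K
}

# cyclic coordinate descent for the lasso in glmnet's parametrization:
# (1 / 2n) ||y - X b||^2 + lambda ||b||_1
cd_lasso <- function(x, y, lam, tol = 1e-14, iters = 100000) {
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  xs <- colSums(x^2) / n
  for (it in seq_len(iters)) {
    dmax <- 0
    for (j in seq_len(p)) {
      r <- y - x[, -j, drop = FALSE] %*% b[-j]
      z <- sum(x[, j] * r) / n
      bn <- sign(z) * max(abs(z) - lam, 0) / xs[j]
      dmax <- max(dmax, abs(bn - b[j]))
      b[j] <- bn
    }
    if (dmax < tol) break
  }
  b
}

# dependent-correlation screening oracle: plain nested loops over all
# candidate pairs and all third variables, Steiger back-transformed z
brute_goldbricker_props <- function(R, n, alpha, cor_min) {
  p <- ncol(R)
  out <- list()
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (abs(R[i, j]) < cor_min) next
    sig <- 0; tot <- 0
    for (k in seq_len(p)) {
      if (k == i || k == j) next
      z1 <- atanh(R[i, k]); z2 <- atanh(R[j, k])
      rb <- tanh((z1 + z2) / 2)
      psi <- R[i, j] * (1 - 2 * rb^2) -
        0.5 * rb^2 * (1 - 2 * rb^2 - R[i, j]^2)
      zst <- sqrt(n - 3) * (z1 - z2) / sqrt(2 - 2 * psi / (1 - rb^2)^2)
      pv <- 2 * pnorm(-abs(zst))
      tot <- tot + 1
      if (pv < alpha) sig <- sig + 1
    }
    out[[paste(i, j)]] <- sig / tot
  }
  out
}

# planted three-block signed network used by the spinglass checks
planted_block_net <- function(within = 0.3, between = 0.02,
                              sizes = c(7, 7, 3)) {
  memb <- rep(seq_along(sizes), sizes)
  p <- sum(sizes)
  w <- matrix(between, p, p)
  for (g in seq_along(sizes)) {
    idx <- which(memb == g)
    w[idx, idx] <- within
  }
  diag(w) <- 0
  list(net = weighted_network(w, paste0("V", seq_len(p))), membership = memb)
}

# small random sparse symmetric weight matrix with |w| < wmax
random_sparse_net <- function(p, n_edges, wmin = 0.02, wmax = 0.4,
                              signed = FALSE) {
  w <- matrix(0, p, p)
  iu <- which(upper.tri(w))
  on <- sample(iu, n_edges)
  vals <- runif(n_edges, wmin, wmax)
  if (signed) vals <- vals * sample(c(-1, 1), n_edges, replace = TRUE)
  w[on] <- vals
  w <- w + t(w)
  weighted_network(w, paste0("V", seq_len(p)))
}

# four-item truth used in several cross-lagged checks: two 2-item
# communities, no within-wave edges (diagonal innovations)
small_clpn_truth <- function(autoregressive = c(0.4, 0, 0.4, 0.4),
                             cross = NULL) {
  generate_truth(synthetic_config(
    community_sizes = c(2L, 2L), within_edge_weight = 0,
    bridge_edges = NULL, cross_lagged = cross,
    autoregressive = autoregressive, threshold_skew = 0.5,
    reverse_coded = rep(FALSE, 4)))
}
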