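#' Correlation of two networks' adjacency and centrality
#'
#' Spearman and Pearson correlations of the vectorized upper-triangle
#' edge weights, and of the EI1/EI2 centrality vectors, with the usual
#' correlation-test p-values.  A correlation of 1 means the networks
#' have a perfect linear relationship, 0 no detectable linear
#' correspondence, and -1 that they are exact opposites.  Constant
#' vectors give `NA` correlations.
#'
#' @param netA,netB [weighted_network()] objects on the same node set.
#' @return data frame of class `similarity_report` with one row per
#'   (quantity, method) combination.
#' @export
adjacency_correlation <- function(netA, netB) {
  stopifnot(inherits(netA, "weighted_network"),
            inherits(netB, "weighted_network"))
  if (!identical(netA$node_labels, netB$node_labels))
    stop("networks must share the same node labels")
  pairs <- list(edges = list(upper_tri(netA$weights),
                             upper_tri(netB$weights)),
                EI1 = list(unname(expected_influence(netA, 1)),
                           unname(expected_influence(netB, 1))),
                EI2 = list(unname(expected_influence(netA, 2)),
                           unname(expected_influence(netB, 2))))
  rows <- list()
  for (q in names(pairs)) {
    a <- pairs[[q]][[1]]; b <- pairs[[q]][[2]]
    for (m in c("spearman", "pearson")) {
      if (sd(a) == 0 || sd(b) == 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(quantity = q, method = m, correlation = NA_real_,
                     p_value = NA_real_,
                     note = "constant vector; correlation undefined")
      } else {
        ct <- suppressWarnings(cor.test(a, b, method = m))
        rows[[length(rows) + 1L]] <-
          data.frame(quantity = q, method = m,
                     correlation = unname(ct$estimate),
                     p_value = ct$p.value, note = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("similarity_report", "data.frame")
  out
}

net_stats <- function(net) {
  w <- net$weights
  list(edges = upper_tri(w),
       global_strength = sum(abs(upper_tri(w))),
       ei1 = rowSums(w))
}

#' Permutation test comparing two networks
#'
#' Re-samples group labels of the pooled participants `n_perm` times;
#' each permutation re-estimates both networks with the full
#' [estimate_network()] configuration and recomputes (i) the maximum
#' absolute edge difference M, (ii) the absolute global-strength
#' difference S, (iii) every per-edge absolute difference, and (iv) every
#' per-node EI1 difference.  p-values use the `(1 + #{perm >= obs}) /
#' (1 + n_perm)` convention; per-edge p-values are Holm-adjusted across
#' edges and per-node p-values across nodes.
#'
#' The two groups are treated as independent samples, as in the standard
#' network comparison test; when the groups are two waves with
#' overlapping participants this is an approximation.
#'
#' @param dataA,dataB [ordinal_panel()] objects on the same items.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param config a [net_config()] used for every estimation.
#' @return object of class `nct_result`.
#' @export
network_structure_test <- function(dataA, dataB, n_perm = 1000L,
                                   seed = 1L, config = net_config()) {
  stopifnot(inherits(dataA, "ordinal_panel"),
            inherits(dataB, "ordinal_panel"))
  if (!identical(dataA$item_labels, dataB$item_labels))
    stop("the two groups must share the same item set")
  nA <- nrow(dataA$responses); nB <- nrow(dataB$responses)
  pooled <- rbind(dataA$responses, dataB$responses)
  est <- function(rows, sub_seed) {
    cfg <- config
    cfg$seed <- sub_seed
    scores <- nonparanormal_transform(pooled[rows, , drop = FALSE])
    estimate_network(scores, cfg)
  }
  # both groups share one rotation-seed per (re)estimation round, so the
  # comparison statistics are symmetric under swapping the groups
  sA <- net_stats(est(seq_len(nA), derive_seed(seed, 1L)))
  sB <- net_stats(est(nA + seq_len(nB), derive_seed(seed, 1L)))
  obs_M <- max(abs(sA$edges - sB$edges))
  obs_S <- abs(sA$global_strength - sB$global_strength)
  obs_edge <- abs(sA$edges - sB$edges)
  obs_ei <- abs(sA$ei1 - sB$ei1)

  ge_M <- 0L; ge_S <- 0L
  ge_edge <- integer(length(obs_edge))
  ge_ei <- integer(length(obs_ei))
  set.seed(derive_seed(seed, 3L))
  perm_seeds <- sample.int(2147483000L, n_perm)
  for (b in seq_len(n_perm)) {
    idxA <- sample.int(nA + nB, nA)
    pA <- net_stats(est(idxA, perm_seeds[b]))
    pB <- net_stats(est(setdiff(seq_len(nA + nB), idxA), perm_seeds[b]))
    d_edge <- abs(pA$edges - pB$edges)
    ge_M <- ge_M + (max(d_edge) >= obs_M)
    ge_S <- ge_S + (abs(pA$global_strength - pB$global_strength) >= obs_S)
    ge_edge <- ge_edge + (d_edge >= obs_edge)
    ge_ei <- ge_ei + (abs(pA$ei1 - pB$ei1) >= obs_ei)
  }
  pval <- function(ge) (1 + ge) / (1 + n_perm)
  labels <- dataA$item_labels
  pair_idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  edge_table <- data.frame(
    item_i = labels[pair_idx[, 1]], item_j = labels[pair_idx[, 2]],
    difference = obs_edge, p_raw = pval(ge_edge),
    p_holm = stats::p.adjust(pval(ge_edge), method = "holm"))
  node_table <- data.frame(
    node = labels, difference = obs_ei, p_raw = pval(ge_ei),
    p_holm = stats::p.adjust(pval(ge_ei), method = "holm"))
  structure(list(M = obs_M, S = obs_S,
                 p_M = pval(ge_M), p_S = pval(ge_S),
                 edge_tests = edge_table, centrality_tests = node_table,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$n_perm, " permutations)\n", sep = "")
  cat("  max edge difference M =", signif(x$M, 4), ", p =",
      signif(x$p_M, 4), "\n")
  cat("  global strength difference S =", signif(x$S, 4), ", p =",
      signif(x$p_S, 4), "\n")
  sig <- sum(x$edge_tests$p_holm < 0.05)
  cat("  edges significant after Holm correction:", sig, "\n")
  invisible(x)
}
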