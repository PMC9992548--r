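net_to_igraph <- function(net, absolute = FALSE) {
  w <- net$weights
  g <- igraph::graph_from_adjacency_matrix(
    if (absolute) abs(w) else w, mode = "undirected", weighted = TRUE,
    diag = FALSE)
  g
}

#' Signed-network Potts Hamiltonian of a partition
#'
#' Negative-edge extension of the configuration-null modularity
#' Hamiltonian: within-community positive weight (relative to the
#' positive configuration null) lowers the energy, within-community
#' negative weight (relative to the negative null) raises it.
#'
#' @param weights symmetric signed weight matrix.
#' @param membership integer community per node.
#' @param gamma,gamma_minus resolution parameters for the positive and
#'   negative parts.
#' @return scalar Hamiltonian; lower is better.
#' @export
signed_hamiltonian <- function(weights, membership, gamma = 1,
                               gamma_minus = 1) {
  wp <- pmax(weights, 0); wn <- pmax(-weights, 0)
  ham_part <- function(w, g) {
    s <- rowSums(w); m2 <- sum(s)
    null <- if (m2 > 0) tcrossprod(s) / m2 else 0 * w
    same <- outer(membership, membership, "==")
    sum(((w - g * null) * same)[upper.tri(w)])
  }
  -(ham_part(wp, gamma) - gamma_minus * ham_part(wn, gamma_minus))
}

#' Spinglass community partition with multiple restarts
#'
#' Minimizes the signed Potts Hamiltonian by simulated annealing
#' (igraph's spinglass algorithm, negative-weight implementation when
#' needed), independently restarted `n_spins` times; the configuration
#' with the lowest [signed_hamiltonian()] is returned, with ties broken
#' by the lexicographically smallest canonical labeling.  Disconnected
#' components are partitioned separately (isolated nodes become
#' singleton communities).
#'
#' @param net a [weighted_network()] with at least one nonzero edge.
#' @param n_spins number of annealing restarts.
#' @param gamma resolution parameter.
#' @param seed integer seed.
#' @param max_communities upper bound on the number of spin states.
#' @return object of class `community_partition`: named integer
#'   `membership`, the `hamiltonian` of the returned configuration,
#'   `n_runs`, `seed`.
#' @export
spinglass_partition <- function(net, n_spins = 500L, gamma = 1,
                                seed = 1L, max_communities = 25L) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  if (all(w == 0)) stop("network has no edges; nothing to partition")
  p <- ncol(w)
  g <- net_to_igraph(net)
  impl <- if (any(w < 0)) "neg" else "orig"
  comps <- igraph::components(g)
  set.seed(seed)
  best <- NULL; best_h <- Inf
  for (run in seq_len(n_spins)) {
    memb <- integer(p)
    offset <- 0L
    for (cc in seq_len(comps$no)) {
      idx <- which(comps$membership == cc)
      if (length(idx) <= 2L) {
        # singleton, or a connected pair: one community (the annealing
        # backend does not handle graphs this small)
        memb[idx] <- offset + 1L
        offset <- offset + 1L
        next
      }
      sub <- igraph::induced_subgraph(g, idx)
      sg <- igraph::cluster_spinglass(
        sub, spins = min(length(idx), max_communities), gamma = gamma,
        implementation = impl)
      memb[idx] <- offset + igraph::membership(sg)
      offset <- offset + max(igraph::membership(sg))
    }
    memb <- canonical_labels(memb)
    h <- signed_hamiltonian(w, memb, gamma)
    if (h < best_h - 1e-12 ||
        (abs(h - best_h) <= 1e-12 && !is.null(best) &&
         lexicographically_smaller(memb, best))) {
      best <- memb; best_h <- h
    }
  }
  structure(list(membership = stats::setNames(best, net$node_labels),
                 hamiltonian = best_h, n_runs = n_spins,
                 gamma = gamma, seed = seed),
            class = "community_partition")
}

canonical_labels <- function(memb) {
  match(memb, unique(memb))
}

lexicographically_smaller <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Spinglass partition:", max(x$membership), "communities over",
      length(x$membership), "nodes (H =", signif(x$hamiltonian, 4),
      ",", x$n_runs, "restarts)\n")
  invisible(x)
}

#' Intensity (geometric-mean weight) of a clique
#'
#' The weighted clique-percolation intensity: the geometric mean of the
#' absolute edge weights over all `k (k - 1) / 2` edges of a complete
#' subgraph.
#'
#' @param net a [weighted_network()].
#' @param nodes node labels or indices forming a clique in the
#'   nonzero-edge graph.
#' @return scalar intensity.
#' @export
clique_intensity <- function(net, nodes) {
  stopifnot(inherits(net, "weighted_network"))
  idx <- if (is.character(nodes)) match(nodes, net$node_labels) else
    as.integer(nodes)
  if (anyNA(idx)) stop("unknown node(s): ",
                       paste(nodes[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("a clique needs at least 2 nodes")
  w <- net$weights[idx, idx]
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[upper.tri(w)]
  if (any(vals == 0)) {
    miss <- pairs[which(vals == 0)[1], ]
    stop("nodes do not form a clique: no edge between ",
         net$node_labels[idx[miss[1]]], " and ",
         net$node_labels[idx[miss[2]]])
  }
  exp(mean(log(abs(vals))))
}

#' Overlapping communities by weighted clique percolation
#'
#' Enumerates all k-cliques of the nonzero-edge graph, retains those
#' whose [clique_intensity()] reaches `I`, links retained cliques that
#' share `k - 1` nodes, and returns the node sets of the resulting
#' clique-graph components.  Nodes belonging to two or more communities
#' are the "percolated" (overlapping) items.
#'
#' @param net a [weighted_network()].
#' @param k clique size (>= 3).
#' @param I intensity threshold.
#' @return object of class `overlap_communities`: `communities` (list of
#'   node-label vectors, each sorted), `membership_count` (named integer
#'   per node), `cliques` (list with nodes and intensity of every
#'   retained clique), and the parameters `k`, `I`.
#' @export
clique_percolation <- function(net, k = 4L, I = 0.08) {
  stopifnot(inherits(net, "weighted_network"))
  if (k < 3) stop("k must be at least 3")
  g <- net_to_igraph(net)
  cl <- igraph::cliques(g, min = k, max = k)
  cl <- lapply(cl, as.integer)
  if (length(cl) > 0) {
    intens <- vapply(cl, function(nodes) clique_intensity(net, nodes),
                     numeric(1))
    # tolerance keeps cliques sitting exactly at the threshold (the
    # geometric mean is computed in the log domain)
    keep <- intens >= I - 1e-12
    cl <- cl[keep]; intens <- intens[keep]
  } else intens <- numeric(0)
  communities <- list()
  if (length(cl) > 0) {
    nc <- length(cl)
    adj <- matrix(FALSE, nc, nc)
    if (nc > 1) {
      for (a in seq_len(nc - 1)) {
        for (b in seq(a + 1, nc)) {
          if (length(intersect(cl[[a]], cl[[b]])) == k - 1)
            adj[a, b] <- adj[b, a] <- TRUE
        }
      }
    }
    cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(cg)$membership
    communities <- lapply(seq_len(max(comp)), function(cc) {
      sort(net$node_labels[sort(unique(unlist(cl[comp == cc])))])
    })
    # deterministic order: by first node label then size
    ord <- order(vapply(communities, `[`, character(1), 1),
                 lengths(communities))
    communities <- communities[ord]
  }
  count <- stats::setNames(integer(length(net$node_labels)),
                           net$node_labels)
  for (comm in communities) count[comm] <- count[comm] + 1L
  structure(list(communities = communities, membership_count = count,
                 cliques = Map(function(nodes, i)
                   list(nodes = net$node_labels[nodes], intensity = i),
                   cl, as.list(intens)),
                 k = as.integer(k), I = I),
            class = "overlap_communities")
}

#' @export
print.overlap_communities <- function(x, ...) {
  cat("Clique percolation (k =", x$k, ", I =", x$I, "):",
      length(x$communities), "communities\n")
  over <- names(x$membership_count)[x$membership_count >= 2]
  if (length(over))
    cat("  percolated (overlapping) items:", paste(over, collapse = ", "),
        "\n")
  invisible(x)
}

#' Percolated (multi-community) items
#' @param oc an `overlap_communities` object.
#' @return character vector of nodes in two or more communities.
#' @export
percolated_items <- function(oc) {
  names(oc$membership_count)[oc$membership_count >= 2]
}
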