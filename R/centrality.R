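#' Expected influence centrality
#'
#' One-step expected influence is the signed sum of a node's edge
#' weights; two-step adds the edge-weighted one-step values of its
#' neighbours:
#' `EI1(i) = sum_j w_ij`, `EI2(i) = EI1(i) + sum_j w_ij EI1(j)`.
#' On an all-positive network EI1 coincides with strength centrality.
#'
#' @param net a [weighted_network()].
#' @param steps 1 or 2.
#' @return named numeric vector.
#' @export
expected_influence <- function(net, steps = 1) {
  stopifnot(inherits(net, "weighted_network"), steps %in% c(1, 2))
  w <- net$weights
  ei1 <- rowSums(w)
  out <- if (steps == 1) ei1 else ei1 + as.numeric(w %*% ei1)
  stats::setNames(out, net$node_labels)
}

#' Bridge expected influence centrality
#'
#' The expected-influence sums restricted to edges crossing community
#' boundaries: `BEI1(i) = sum_{j : comm(j) != comm(i)} w_ij`, and
#' `BEI2(i) = BEI1(i) + sum_{j : comm(j) != comm(i)} w_ij BEI1(j)`.
#' Identifies symptoms that transmit activation between disorders.
#'
#' @param net a [weighted_network()].
#' @param partition a [spinglass_partition()] result, or a named vector
#'   mapping every node to a community.
#' @param steps 1 or 2.
#' @return named numeric vector.
#' @export
bridge_expected_influence <- function(net, partition, steps = 1) {
  stopifnot(inherits(net, "weighted_network"), steps %in% c(1, 2))
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  if (is.null(names(memb))) names(memb) <- net$node_labels
  if (!all(net$node_labels %in% names(memb)))
    stop("partition is missing node(s): ",
         paste(setdiff(net$node_labels, names(memb)), collapse = ", "))
  memb <- memb[net$node_labels]
  w <- net$weights
  cross <- outer(memb, memb, "!=")
  wb <- w * cross
  bei1 <- rowSums(wb)
  out <- if (steps == 1) bei1 else bei1 + as.numeric(wb %*% bei1)
  stats::setNames(out, net$node_labels)
}

#' Node predictability
#'
#' Proportion of each node's variance explained by its network
#' neighbours: the R-squared of the least-squares regression of the
#' node's (transformed) scores on the scores of all nodes it shares a
#' nonzero edge with.  Nodes without neighbours get 0; collinear
#' neighbour columns are dropped with a warning.
#'
#' @param scores `gaussian_scores` (or numeric matrix) with columns
#'   matching the network's nodes.
#' @param net a [weighted_network()].
#' @return named numeric vector of R-squared values in `[0, 1]`.
#' @export
predictability <- function(scores, net) {
  stopifnot(inherits(net, "weighted_network"))
  x <- as.matrix(scores)
  if (!all(net$node_labels %in% colnames(x)))
    stop("scores do not cover all network nodes")
  x <- x[, net$node_labels, drop = FALSE]
  w <- net$weights
  r2 <- vapply(seq_len(ncol(x)), function(i) {
    nb <- which(w[i, ] != 0)
    if (length(nb) == 0) return(0)
    X <- cbind(1, x[, nb, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      warning("collinear neighbour columns dropped for node ",
              net$node_labels[i])
    fit <- qr.fitted(qrX, x[, i])
    y <- x[, i]
    1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  stats::setNames(pmin(pmax(r2, 0), 1), net$node_labels)
}

#' Per-node centrality table
#'
#' Assembles EI1/EI2, bridge EI1/EI2 against the supplied partition,
#' their z-standardized versions, and (when scores are given) node
#' predictability.
#'
#' @param net a [weighted_network()].
#' @param partition community partition for the bridge statistics.
#' @param scores optional score matrix for [predictability()].
#' @return data frame of class `centrality_table`.
#' @export
centrality_table <- function(net, partition, scores = NULL) {
  zs <- function(x) if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
  ei1 <- expected_influence(net, 1)
  ei2 <- expected_influence(net, 2)
  bei1 <- bridge_expected_influence(net, partition, 1)
  bei2 <- bridge_expected_influence(net, partition, 2)
  out <- data.frame(node = net$node_labels,
                    EI1 = ei1, EI2 = ei2, BEI1 = bei1, BEI2 = bei2,
                    EI1_z = zs(ei1), EI2_z = zs(ei2),
                    BEI1_z = zs(bei1), BEI2_z = zs(bei2))
  if (!is.null(scores)) out$predictability <- predictability(scores, net)
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  out$community <- memb[net$node_labels]
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}
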