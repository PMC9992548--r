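#' Default item labels for the 17-item anxiety/depression/loneliness panel
#'
#' Seven generalized-anxiety items (A1-A7), seven depressive-symptom items
#' (D1-D7) and three loneliness items (L1-L3), following the short
#' GAD-7 / CES-D / UCLA-3 instruments administered in two-wave surveys of
#' older adults.
#'
#' @param community_sizes integer vector of community sizes.
#' @return character vector of item labels.
#' @export
default_item_labels <- function(community_sizes = c(7L, 7L, 3L)) {
  prefixes <- c("A", "D", "L", "X", "Y", "Z")[seq_along(community_sizes)]
  unlist(lapply(seq_along(community_sizes),
                function(g) paste0(prefixes[g], seq_len(community_sizes[g]))))
}

default_community_names <- function(k) {
  c("anxiety", "depression", "loneliness",
    paste0("community", seq_len(max(0, k - 3)) + 3))[seq_len(k)]
}

#' Configuration of the synthetic two-wave ordinal panel generator
#'
#' Describes a ground-truth latent Gaussian graphical model shared by the
#' two waves, a sparse cross-lagged (T1 to T2) coefficient matrix, and
#' item thresholds that discretize the latent scores into ordered
#' categories.  Within each community the nonzero partial correlations
#' form a ring (each item tied to its two community neighbours), which
#' keeps the implied precision matrix positive definite at the default
#' edge weight; cross-community "bridge" edges and cross-lagged paths are
#' listed explicitly.
#'
#' The defaults emulate the study conditions of a two-wave COVID-19-era
#' panel of older adults: 17 items in three communities (7 anxiety, 7
#' depression, 3 loneliness), four response categories with strongly
#' skewed marginals (anxiety and loneliness items piled on the lowest
#' category, reverse-coded depression items on the highest), within-wave
#' partial correlations of 0.25, four weak bridges linking the
#' communities, autoregressive paths of 0.4 everywhere except the
#' "feeling nervous" item A1, and three cross-lagged paths from
#' loneliness/anhedonia items into A1 and L2.
#'
#' @param n_participants default number of participants simulated.
#' @param community_sizes integer sizes of the communities (sum = p).
#' @param within_edge_weight partial correlation of within-community ring
#'   edges.
#' @param bridge_edges data frame with columns `from`, `to`, `weight`
#'   giving cross-community partial correlations (labels or indices), or
#'   `NULL` for none.
#' @param cross_lagged data frame with columns `from`, `to`, `weight`
#'   giving standardized cross-lagged coefficients (T1 item predicting a
#'   different T2 item), or `NULL` for none.
#' @param autoregressive scalar or length-p vector of standardized
#'   autoregressive coefficients in `[0, 1)`.
#' @param n_categories number of ordered response categories per item.
#' @param threshold_skew scalar shift of the category thresholds;
#'   positive values push mass into the lowest category (reverse-coded
#'   items are shifted the opposite way).
#' @param reverse_coded logical length-p vector marking reverse-coded
#'   items; default marks the depression community.
#' @param seed integer seed recorded with the configuration.
#' @return object of class `syn_config`.
#' @seealso [generate_truth()], [simulate_panel()]
#' @export
synthetic_config <- function(n_participants = 2000L,
                             community_sizes = c(7L, 7L, 3L),
                             within_edge_weight = 0.25,
                             bridge_edges = default_bridge_edges(),
                             cross_lagged = default_cross_lagged(),
                             autoregressive = default_autoregressive(),
                             n_categories = 4L,
                             threshold_skew = 0.8,
                             reverse_coded = NULL,
                             seed = 1L) {
  p <- sum(community_sizes)
  if (p < 2) stop("need at least 2 items")
  if (n_categories < 2) stop("need at least 2 response categories")
  labels <- default_item_labels(community_sizes)
  comm <- rep(default_community_names(length(community_sizes)),
              times = community_sizes)
  names(comm) <- labels
  if (is.null(reverse_coded)) {
    reverse_coded <- comm == "depression"
  }
  if (length(autoregressive) == 1L) autoregressive <- rep(autoregressive, p)
  if (length(autoregressive) != p)
    stop("autoregressive must be a scalar or length-p vector")
  if (any(autoregressive < 0 | autoregressive >= 1))
    stop("autoregressive coefficients must lie in [0, 1)")
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         community_sizes = as.integer(community_sizes),
         p = p,
         item_labels = labels,
         community_labels = comm,
         within_edge_weight = within_edge_weight,
         bridge_edges = normalize_edge_df(bridge_edges, labels),
         cross_lagged = normalize_edge_df(cross_lagged, labels),
         autoregressive = autoregressive,
         n_categories = as.integer(n_categories),
         threshold_skew = threshold_skew,
         reverse_coded = reverse_coded,
         seed = as.integer(seed)),
    class = "syn_config")
  # fail early if the implied precision matrix is not positive definite
  invisible(truth_precision(cfg))
  cfg
}

#' @rdname synthetic_config
#' @export
default_bridge_edges <- function() {
  data.frame(from = c("A2", "A4", "D5", "D4"),
             to = c("D1", "D1", "L1", "L2"),
             weight = 0.15)
}

#' @rdname synthetic_config
#' @export
default_cross_lagged <- function() {
  data.frame(from = c("L3", "L2", "D6"),
             to = c("A1", "A1", "L2"),
             weight = c(0.37, 0.28, 0.30))
}

#' @rdname synthetic_config
#' @export
default_autoregressive <- function() {
  a <- rep(0.4, 17)
  a[1] <- 0   # A1: no autoregressive path
  a
}

normalize_edge_df <- function(edges, labels) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0))
    return(data.frame(from = character(), to = character(),
                      weight = numeric()))
  if (!is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, function(e)
      data.frame(from = e[[1]], to = e[[2]], weight = as.numeric(e[[3]]))))
  to_label <- function(x) {
    if (is.numeric(x)) labels[x] else as.character(x)
  }
  out <- data.frame(from = to_label(edges$from), to = to_label(edges$to),
                    weight = as.numeric(edges$weight))
  bad <- !(out$from %in% labels) | !(out$to %in% labels)
  if (any(bad)) stop("unknown item labels in edge list: ",
                     paste(unique(c(out$from[bad], out$to[bad])),
                           collapse = ", "))
  if (any(out$from == out$to)) stop("self edges are not allowed")
  out
}

# ring edges within each community: i -- i+1, plus closing edge for m >= 3
within_edge_index <- function(community_sizes) {
  off <- cumsum(c(0L, community_sizes))
  out <- NULL
  for (g in seq_along(community_sizes)) {
    m <- community_sizes[g]
    if (m < 2) next
    i <- off[g] + seq_len(m - 1L)
    e <- cbind(i, i + 1L)
    if (m >= 3) e <- rbind(e, c(off[g] + m, off[g] + 1L))
    out <- rbind(out, e)
  }
  out
}

truth_precision <- function(cfg) {
  p <- cfg$p
  K <- diag(p)
  we <- within_edge_index(cfg$community_sizes)
  if (!is.null(we)) {
    for (r in seq_len(nrow(we))) {
      K[we[r, 1], we[r, 2]] <- K[we[r, 2], we[r, 1]] <-
        -cfg$within_edge_weight
    }
  }
  be <- cfg$bridge_edges
  if (nrow(be) > 0) {
    idx_from <- match(be$from, cfg$item_labels)
    idx_to <- match(be$to, cfg$item_labels)
    for (r in seq_len(nrow(be))) {
      K[idx_from[r], idx_to[r]] <- K[idx_to[r], idx_from[r]] <- -be$weight[r]
    }
  }
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop("configured edge weights imply a non-positive-definite precision ",
         "matrix (smallest eigenvalue ", signif(ev_min, 4), ")")
  K
}

#' Construct the ground truth implied by a synthetic configuration
#'
#' Builds the within-wave precision matrices (identical structure at both
#' waves), the implied partial-correlation and correlation matrices, the
#' cross-wave standardized coefficient matrix and the category thresholds.
#' The latent T1 scores have a correlation-matrix covariance; the wave-2
#' innovation covariance is scaled so that latent T2 marginals also have
#' unit variance, making the configured cross-lagged coefficients
#' standardized.
#'
#' @param config a [synthetic_config()] object.
#' @return object of class `syn_truth` with elements `precision_T1`,
#'   `precision_T2`, `pcor_T1`, `pcor_T2`, `sigma_T1`, `sigma_T2`,
#'   `beta_cross`, `beta_full` (autoregressive diagonal plus cross paths),
#'   `innovation_sd`, `thresholds`, `item_labels`, `community_labels`,
#'   `seed` and the originating `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  p <- config$p
  K0 <- truth_precision(config)
  sigma0 <- solve(K0)
  d <- sqrt(diag(sigma0))
  sigma <- sigma0 / tcrossprod(d)
  diag(sigma) <- 1
  sigma <- (sigma + t(sigma)) / 2
  precision <- K0 * tcrossprod(d)   # exact inverse of the correlation matrix
  pc <- pcor_from_precision(precision)

  beta_cross <- matrix(0, p, p,
                       dimnames = list(config$item_labels,
                                       config$item_labels))
  cl <- config$cross_lagged
  if (nrow(cl) > 0) {
    for (r in seq_len(nrow(cl)))
      beta_cross[cl$from[r], cl$to[r]] <- cl$weight[r]
  }
  beta_full <- beta_cross
  diag(beta_full) <- config$autoregressive

  # predictor variance of each T2 latent; innovations rescaled to make
  # latent T2 marginals unit-variance
  v <- diag(t(beta_full) %*% sigma %*% beta_full)
  if (any(v >= 1))
    stop("cross-lagged/autoregressive coefficients imply latent T2 ",
         "variance >= 1 before noise for item(s) ",
         paste(config$item_labels[v >= 1], collapse = ", "))
  innovation_sd <- sqrt(1 - v)

  ncat <- config$n_categories
  base <- qnorm(seq_len(ncat - 1L) / ncat)
  shift <- ifelse(config$reverse_coded, -config$threshold_skew,
                  config$threshold_skew)
  thresholds <- t(vapply(shift, function(s) base + s, numeric(ncat - 1L)))
  rownames(thresholds) <- config$item_labels

  structure(
    list(precision_T1 = precision, precision_T2 = precision,
         pcor_T1 = pc, pcor_T2 = pc,
         sigma_T1 = sigma, sigma_T2 = sigma,
         beta_cross = beta_cross, beta_full = beta_full,
         innovation_sd = innovation_sd,
         thresholds = thresholds,
         item_labels = config$item_labels,
         community_labels = config$community_labels,
         reverse_coded = config$reverse_coded,
         n_categories = ncat,
         seed = config$seed,
         config = config),
    class = "syn_truth")
}

pcor_from_precision <- function(K) {
  d <- sqrt(diag(K))
  pc <- -K / tcrossprod(d)
  diag(pc) <- 0
  pc
}

#' Simulate a paired two-wave ordinal panel from a ground truth
#'
#' Latent wave-1 scores are drawn from a multivariate normal with the
#' truth's correlation matrix; latent wave-2 scores are the cross-lagged
#' linear map of wave 1 plus correlated innovations scaled so T2 latent
#' marginals have unit variance.  Each latent score is discretized by the
#' item's thresholds into categories `1..n_categories`.
#'
#' @param truth a [generate_truth()] result.
#' @param n number of participants (>= 10).
#' @param seed integer seed; same truth and seed give identical output.
#' @return object of class `panel_pair`: list with `T1` and `T2`
#'   [ordinal_panel()] objects sharing participants, plus attribute
#'   `latent` (list of the underlying latent score matrices, kept for
#'   diagnostics and oracle checks).
#' @export
simulate_panel <- function(truth, n, seed = truth$seed) {
  stopifnot(inherits(truth, "syn_truth"))
  n <- as.integer(n)
  if (n < 10) stop("n must be at least 10")
  p <- length(truth$item_labels)
  set.seed(seed)
  R1 <- chol(truth$sigma_T1)
  z1 <- matrix(rnorm(n * p), n, p) %*% R1
  sigma_e <- truth$sigma_T2 * tcrossprod(truth$innovation_sd)
  e <- matrix(rnorm(n * p), n, p) %*% chol(sigma_e)
  z2 <- z1 %*% truth$beta_full + e
  colnames(z1) <- colnames(z2) <- truth$item_labels

  discretize <- function(z) {
    resp <- vapply(seq_len(p), function(j)
      findInterval(z[, j], truth$thresholds[j, ]) + 1L, integer(n))
    colnames(resp) <- truth$item_labels
    resp
  }
  pair <- structure(
    list(T1 = ordinal_panel(discretize(z1), truth$item_labels,
                            truth$community_labels, wave_id = "T1",
                            reverse_coded = truth$reverse_coded,
                            n_categories = truth$n_categories),
         T2 = ordinal_panel(discretize(z2), truth$item_labels,
                            truth$community_labels, wave_id = "T2",
                            reverse_coded = truth$reverse_coded,
                            n_categories = truth$n_categories)),
    class = "panel_pair")
  attr(pair, "latent") <- list(T1 = z1, T2 = z2)
  attr(pair, "seed") <- seed
  pair
}

#' Write / read a paired panel as a wide CSV
#'
#' One row per participant; columns are the item labels suffixed
#' `_T1` / `_T2`.
#'
#' @param pair a `panel_pair`.
#' @param path CSV file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `panel_pair` (without latent scores).
#' @export
write_panel_csv <- function(pair, path) {
  stopifnot(inherits(pair, "panel_pair"))
  df <- cbind(as.data.frame(pair$T1$responses),
              as.data.frame(pair$T2$responses))
  names(df) <- c(paste0(pair$T1$item_labels, "_T1"),
                 paste0(pair$T2$item_labels, "_T2"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param community_labels named character vector mapping items to
#'   communities; defaults to the standard 17-item map when the labels
#'   match, otherwise a single community.
#' @param n_categories number of response categories.
#' @export
read_panel_csv <- function(path, community_labels = NULL,
                           n_categories = NULL) {
  df <- read.csv(path, check.names = FALSE)
  cols <- names(df)
  t1 <- grep("_T1$", cols, value = TRUE)
  t2 <- grep("_T2$", cols, value = TRUE)
  if (length(t1) == 0 || length(t1) != length(t2))
    stop("expected matching *_T1 and *_T2 columns in ", path)
  items <- sub("_T1$", "", t1)
  if (!identical(items, sub("_T2$", "", t2)))
    stop("T1/T2 item columns do not match in ", path)
  # listwise deletion of incomplete rows at load time
  keep <- stats::complete.cases(df[, c(t1, t2)])
  df <- df[keep, , drop = FALSE]
  m1 <- as.matrix(df[, t1]); m2 <- as.matrix(df[, t2])
  dimnames(m1) <- list(NULL, items)
  dimnames(m2) <- list(NULL, items)
  if (is.null(community_labels)) {
    std <- default_item_labels()
    if (identical(sort(items), sort(std))) {
      community_labels <- rep(default_community_names(3), c(7, 7, 3))
      names(community_labels) <- std
      community_labels <- community_labels[items]
    } else {
      community_labels <- stats::setNames(rep("all", length(items)), items)
    }
  }
  if (is.null(n_categories)) n_categories <- max(m1, m2)
  structure(
    list(T1 = ordinal_panel(m1, items, community_labels, "T1",
                            n_categories = n_categories),
         T2 = ordinal_panel(m2, items, community_labels, "T2",
                            n_categories = n_categories)),
    class = "panel_pair")
}

#' Write / read ground truth as JSON
#'
#' @param truth a `syn_truth`.
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "syn_truth"))
  obj <- list(item_labels = truth$item_labels,
              community_labels = as.list(truth$community_labels),
              precision_T1 = truth$precision_T1,
              precision_T2 = truth$precision_T2,
              pcor_T1 = truth$pcor_T1,
              beta_full = truth$beta_full,
              thresholds = truth$thresholds,
              n_categories = truth$n_categories,
              seed = truth$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.syn_truth <- function(x, ...) {
  cat("Synthetic two-wave ground truth\n")
  cat("  items:", length(x$item_labels), "in",
      length(unique(x$community_labels)), "communities\n")
  cat("  within-wave edges:", sum(x$pcor_T1[upper.tri(x$pcor_T1)] != 0),
      "\n")
  cat("  cross-lagged paths:", sum(x$beta_cross != 0),
      "| autoregressive:", sum(diag(x$beta_full) != 0), "\n")
  invisible(x)
}

#' @export
print.panel_pair <- function(x, ...) {
  cat("Paired two-wave ordinal panel:", nrow(x$T1$responses),
      "participants,", ncol(x$T1$responses), "items per wave\n")
  invisible(x)
}
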