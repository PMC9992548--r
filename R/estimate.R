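#' Signed partial-correlation network
#'
#' A symmetric p x p matrix of regularized partial correlations with
#' zero diagonal, node labels, optional community labels and estimation
#' metadata.  Validity: symmetry to 1e-10, all |w| < 1, zero diagonal.
#'
#' @param weights symmetric numeric matrix.
#' @param node_labels length-p character vector.
#' @param communities optional named character vector (node -> community).
#' @param metadata list of estimation settings (selected lambda,
#'   criterion, n, ...).
#' @return object of class `weighted_network`.
#' @export
weighted_network <- function(weights, node_labels = colnames(weights),
                             communities = NULL, metadata = list()) {
  weights <- as.matrix(weights)
  check_symmetric(weights, 1e-10, "weight matrix")
  if (any(abs(diag(weights)) > 1e-12))
    stop("weight matrix must have a zero diagonal")
  diag(weights) <- 0
  if (any(abs(weights) >= 1))
    stop("partial correlations must have absolute value < 1")
  if (is.null(node_labels))
    node_labels <- paste0("V", seq_len(ncol(weights)))
  dimnames(weights) <- list(node_labels, node_labels)
  if (!is.null(communities)) {
    if (is.null(names(communities))) names(communities) <- node_labels
    communities <- communities[node_labels]
  }
  structure(list(weights = weights, node_labels = node_labels,
                 communities = communities, metadata = metadata),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Partial-correlation network:", length(x$node_labels), "nodes,",
      ne, "edges\n")
  md <- x$metadata
  if (!is.null(md$lambda))
    cat("  lambda =", signif(md$lambda, 4),
        "(", md$criterion %||% "?", "), n =", md$n %||% NA, "\n")
  invisible(x)
}

#' Penalty sequence for the graphical lasso path
#'
#' Log-spaced decreasing sequence from the saturation point (largest
#' absolute off-diagonal of S, above which the estimate is empty) down to
#' `min_ratio` times it.
#'
#' @param S correlation/covariance matrix.
#' @param n_lambda path length.
#' @param min_ratio smallest lambda as a fraction of the largest.
#' @return decreasing numeric vector.
#' @export
lambda_sequence <- function(S, n_lambda = 100L, min_ratio = 0.01) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 1e-4
  out <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
  out[1] <- lmax   # exp(log(x)) can undershoot by one ulp
  out
}

#' Graphical lasso at a single penalty
#'
#' L1-penalized Gaussian maximum likelihood for the precision matrix:
#' maximizes `log det K - tr(S K) - lambda * sum_{i != j} |K_ij|` with an
#' unpenalized diagonal, by block coordinate descent.
#'
#' @param S symmetric covariance/correlation matrix.
#' @param lambda scalar penalty (off-diagonal entries).
#' @param tol convergence tolerance on the maximum coordinate change.
#' @param maxit maximum number of outer sweeps.
#' @param warm optional list with `w` and `beta` from a previous fit at a
#'   nearby lambda.
#' @return list with precision `wi`, covariance estimate `w`, `niter`,
#'   `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, maxit = 1000L, warm = NULL) {
  check_symmetric(S, 1e-8, "S")
  p <- ncol(S)
  L <- matrix(lambda, p, p); diag(L) <- 0
  fit <- glasso_cpp(S, L, tol, as.integer(maxit),
                    warm$w %||% NULL, warm$beta %||% NULL)
  if (!fit$converged)
    stop("graphical lasso did not converge at lambda = ", signif(lambda, 4),
         " after ", maxit, " sweeps")
  dimnames(fit$wi) <- dimnames(fit$w) <- dimnames(S)
  fit
}

#' Penalized log-likelihood objective of a glasso solution
#'
#' @param K precision matrix.
#' @param S sample covariance.
#' @param lambda penalty.
#' @return `log det K - tr(S K) - lambda * sum_{i != j} |K_ij|`.
#' @export
glasso_objective <- function(K, S, lambda) {
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  off <- sum(abs(K)) - sum(abs(diag(K)))
  as.numeric(ld$modulus) - sum(S * K) - lambda * off
}

#' Graphical lasso solution path
#'
#' Fits the graphical lasso over a decreasing penalty sequence with warm
#' starts, recording the precision matrix and edge count at each lambda.
#'
#' @param scores a `gaussian_scores` matrix (or any numeric matrix whose
#'   correlation matrix defines the model).
#' @param lambdas decreasing penalty sequence; default
#'   [lambda_sequence()] of length `n_lambda`.
#' @param n_lambda,min_ratio used when `lambdas` is `NULL`.
#' @param tol,maxit passed to [glasso_fit()].
#' @return object of class `lambda_path`: list with `lambdas`,
#'   `precision` (list of matrices), `n_edges`, `S`, `n`.
#' @export
glasso_path <- function(scores, lambdas = NULL, n_lambda = 100L,
                        min_ratio = 0.01, tol = 1e-4, maxit = 1000L) {
  x <- as.matrix(scores)
  if (ncol(x) < 3) stop("need at least 3 variables")
  if (nrow(x) <= ncol(x))
    warning("n <= p; the regularization path may be unstable")
  S <- cor(x)
  if (is.null(lambdas)) lambdas <- lambda_sequence(S, n_lambda, min_ratio)
  if (is.unsorted(rev(lambdas))) stop("lambdas must be strictly decreasing")
  precision <- vector("list", length(lambdas))
  n_edges <- integer(length(lambdas))
  warm <- NULL
  for (i in seq_along(lambdas)) {
    fit <- glasso_fit(S, lambdas[i], tol = tol, maxit = maxit, warm = warm)
    precision[[i]] <- fit$wi
    n_edges[i] <- sum(fit$wi[upper.tri(fit$wi)] != 0)
    warm <- fit
  }
  structure(list(lambdas = lambdas, precision = precision,
                 n_edges = n_edges, S = S, n = nrow(x)),
            class = "lambda_path")
}

#' Rotation-based null penalty level
#'
#' Independently permutes the rows of every column (destroying all
#' cross-column dependence while keeping marginals) and records the
#' maximum absolute off-diagonal correlation of the rotated data; the
#' returned penalty is the mean of those maxima over `n_rotations`
#' rotations.  A graphical lasso at this penalty excludes, on average,
#' everything a dependence-free version of the data could produce.
#'
#' @param scores numeric matrix.
#' @param n_rotations number of rotations.
#' @param seed integer seed.
#' @return scalar penalty level `lambda_star`.
#' @export
ric_lambda <- function(scores, n_rotations = 20L, seed = 1L) {
  x <- as.matrix(scores)
  set.seed(seed)
  maxima <- rotation_maxcor_cpp(x, as.integer(n_rotations))
  mean(maxima)
}

#' Select the path penalty by the rotation information criterion
#'
#' @param scores the score matrix the path was fit on.
#' @param path a [glasso_path()] result.
#' @param n_rotations,seed passed to [ric_lambda()].
#' @return list with `lambda_star`, the selected path `lambda` (smallest
#'   path value at or above `lambda_star`) and its `index`.
#' @export
select_ric <- function(scores, path, n_rotations = 20L, seed = 1L) {
  stopifnot(inherits(path, "lambda_path"), length(path$lambdas) > 0)
  lstar <- ric_lambda(scores, n_rotations, seed)
  ok <- which(path$lambdas >= lstar)
  if (length(ok) == 0) {
    warning("rotation penalty ", signif(lstar, 4),
            " exceeds the whole path; returning the largest lambda")
    idx <- 1L
  } else {
    idx <- max(ok)   # lambdas decreasing: last index >= lstar is smallest
  }
  list(lambda_star = lstar, lambda = path$lambdas[idx], index = idx)
}

#' Partial correlations from a precision matrix
#'
#' The Gaussian graphical model identity
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` with a zeroed diagonal.
#'
#' @param K positive-definite precision matrix.
#' @param node_labels,communities,metadata passed to
#'   [weighted_network()].
#' @return a [weighted_network()].
#' @export
precision_to_pcor <- function(K, node_labels = colnames(K),
                              communities = NULL, metadata = list()) {
  check_symmetric(K, 1e-8, "precision matrix")
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) stop("precision matrix is not positive definite")
  pc <- pcor_from_precision(K)
  pc <- (pc + t(pc)) / 2
  weighted_network(pc, node_labels, communities, metadata)
}

#' Estimation settings for the contemporaneous network
#'
#' @param n_lambda path length.
#' @param min_ratio smallest / largest path lambda.
#' @param n_rotations rotations for the RIC.
#' @param criterion `"ric"` (rotation information criterion) or `"ebic"`
#'   (extended BIC with `ebic_gamma`).
#' @param ebic_gamma EBIC hyperparameter.
#' @param tol,maxit glasso convergence settings.
#' @param seed seed for the rotation draws.
#' @return list of class `net_config`.
#' @export
net_config <- function(n_lambda = 100L, min_ratio = 0.01,
                       n_rotations = 20L, criterion = c("ric", "ebic"),
                       ebic_gamma = 0.5, tol = 1e-4, maxit = 1000L,
                       seed = 1L) {
  criterion <- match.arg(criterion)
  structure(list(n_lambda = as.integer(n_lambda), min_ratio = min_ratio,
                 n_rotations = as.integer(n_rotations),
                 criterion = criterion, ebic_gamma = ebic_gamma,
                 tol = tol, maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Estimate a regularized partial-correlation network from ordinal data
#'
#' The full contemporaneous pipeline: nonparanormal transform of the
#' ordinal responses, correlation matrix, graphical lasso with penalty
#' selected by the rotation information criterion (or EBIC), and
#' conversion of the selected precision matrix to partial correlations.
#'
#' With the RIC the selected penalty depends only on the data and the
#' rotation draws, so only the single selected lambda needs a glasso
#' fit; the full path remains available through [glasso_path()].
#'
#' @param data an [ordinal_panel()], a `gaussian_scores` matrix, or a
#'   plain numeric matrix of already-continuous scores.
#' @param config a [net_config()].
#' @return a [weighted_network()] with full estimation metadata.
#' @export
estimate_network <- function(data, config = net_config()) {
  if (inherits(data, "ordinal_panel")) {
    scores <- nonparanormal_transform(data)
    communities <- data$community_labels
  } else {
    scores <- as.matrix(data)
    communities <- NULL
  }
  S <- cor(scores)
  lambdas <- lambda_sequence(S, config$n_lambda, config$min_ratio)
  if (config$criterion == "ric") {
    sel <- list(lambda_star = ric_lambda(scores, config$n_rotations,
                                         config$seed))
    ok <- which(lambdas >= sel$lambda_star)
    sel$index <- if (length(ok) == 0) 1L else max(ok)
    sel$lambda <- lambdas[sel$index]
    fit <- glasso_fit(S, sel$lambda, tol = config$tol, maxit = config$maxit)
    K <- fit$wi
  } else {
    path <- glasso_path(scores, lambdas, tol = config$tol,
                        maxit = config$maxit)
    n <- nrow(scores); p <- ncol(scores)
    ebic <- vapply(seq_along(lambdas), function(i) {
      K <- path$precision[[i]]
      ll <- (n / 2) * (as.numeric(determinant(K)$modulus) - sum(S * K))
      E <- path$n_edges[i]
      -2 * ll + E * log(n) + 4 * config$ebic_gamma * E * log(p)
    }, numeric(1))
    sel <- list(index = which.min(ebic), lambda_star = NA_real_)
    sel$lambda <- lambdas[sel$index]
    K <- path$precision[[sel$index]]
  }
  md <- list(lambda = sel$lambda, lambda_star = sel$lambda_star,
             index = sel$index, criterion = config$criterion,
             n = nrow(scores), n_lambda = config$n_lambda,
             n_rotations = config$n_rotations, seed = config$seed,
             estimator = "glasso",
             note = paste("RIC aggregation: mean of per-rotation maxima;",
                          "glasso variant of the huge-style estimator"))
  precision_to_pcor(K, colnames(S), communities, md)
}
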