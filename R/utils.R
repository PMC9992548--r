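`%||%` <- function(x, y) if (is.null(x)) y else x

#' Upper-triangle vector of a symmetric matrix
#'
#' Column-major order, diagonal excluded; the standard vectorization used
#' when correlating two adjacency matrices or tracking edges across
#' bootstrap replicates.
#'
#' @param m square matrix.
#' @return numeric vector of length `p (p - 1) / 2`.
#' @export
upper_tri <- function(m) m[upper.tri(m)]

#' Derive a stage-specific seed from a global seed
#'
#' Every source of randomness in the pipeline draws its seed from the
#' single global seed through this map, so that stages are reproducible
#' individually and jointly.  The offset is a fixed per-stage integer.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563) + 1L
}

stop_if_not_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
}

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  stop_if_not_square(m, what)
  if (max(abs(m - t(m))) > tol)
    stop(what, " is not symmetric (tolerance ", tol, ")", call. = FALSE)
}

is_pos_def <- function(m, tol = 0) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

#' Sample moment skewness and excess kurtosis
#'
#' @param x numeric vector.
#' @return named vector with `skewness` (m3 / m2^(3/2)) and `kurtosis`
#'   (m4 / m2^2 - 3, i.e. excess kurtosis).
#' @export
moment_shape <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- sum(d^2) / n
  if (m2 == 0) return(c(skewness = NA_real_, kurtosis = NA_real_))
  c(skewness = (sum(d^3) / n) / m2^1.5,
    kurtosis = (sum(d^4) / n) / m2^2 - 3)
}
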