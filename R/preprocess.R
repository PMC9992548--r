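#' Single-wave ordinal item dataset
#'
#' Container for an n x p matrix of ordinal responses coded
#' `1..n_categories`, with item labels, a community (instrument) label
#' per item, and reverse-coding flags.  Rows with missing values must be
#' removed before construction (listwise deletion happens at load time);
#' items observed in fewer than two categories are rejected.
#'
#' @param responses integer matrix, participants in rows.
#' @param item_labels length-p character vector.
#' @param community_labels named character vector (item -> community).
#' @param wave_id `"T1"` or `"T2"`.
#' @param reverse_coded logical length-p vector.
#' @param n_categories number of response categories.
#' @return object of class `ordinal_panel`.
#' @export
ordinal_panel <- function(responses, item_labels = colnames(responses),
                          community_labels = NULL, wave_id = "T1",
                          reverse_coded = NULL, n_categories = max(responses)) {
  responses <- as.matrix(responses)
  if (is.null(item_labels))
    item_labels <- paste0("V", seq_len(ncol(responses)))
  colnames(responses) <- item_labels
  if (anyNA(responses))
    stop("responses contain missing values; apply listwise deletion first")
  if (any(responses < 1 | responses > n_categories))
    stop("responses must be coded 1..", n_categories)
  if (any(responses != round(responses)))
    stop("responses must be integer category codes")
  n_obs_cat <- apply(responses, 2, function(x) length(unique(x)))
  if (any(n_obs_cat < 2))
    stop("zero-variance item(s): ",
         paste(item_labels[n_obs_cat < 2], collapse = ", "))
  if (is.null(community_labels))
    community_labels <- stats::setNames(rep("all", length(item_labels)),
                                        item_labels)
  if (is.null(names(community_labels))) names(community_labels) <- item_labels
  if (is.null(reverse_coded)) reverse_coded <- rep(FALSE, length(item_labels))
  structure(
    list(responses = storage_int(responses), item_labels = item_labels,
         community_labels = community_labels[item_labels],
         wave_id = wave_id, reverse_coded = reverse_coded,
         n_categories = as.integer(n_categories)),
    class = "ordinal_panel")
}

storage_int <- function(m) { storage.mode(m) <- "integer"; m }

#' @export
print.ordinal_panel <- function(x, ...) {
  cat("Ordinal panel (", x$wave_id, "): ", nrow(x$responses),
      " participants x ", length(x$item_labels), " items, ",
      x$n_categories, " categories\n", sep = "")
  invisible(x)
}

#' Item-level descriptive statistics
#'
#' Mean, standard deviation (n - 1 denominator), moment skewness, excess
#' kurtosis, and the item-rest correlation of each item with the sum of
#' the remaining items of its own instrument (community).
#'
#' @param data an [ordinal_panel()].
#' @return data frame of class `descriptives_table` with one row per item.
#' @export
compute_descriptives <- function(data) {
  stopifnot(inherits(data, "ordinal_panel"))
  x <- data$responses
  comm <- data$community_labels
  single <- names(table(comm))[table(comm) < 2]
  if (length(single) > 0)
    stop("item-rest correlation undefined for single-item scale(s): ",
         paste(single, collapse = ", "))
  out <- lapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    shape <- moment_shape(xj)
    same <- setdiff(which(comm == comm[j]), j)
    rest <- rowSums(x[, same, drop = FALSE])
    data.frame(item = data$item_labels[j],
               community = unname(comm[j]),
               mean = mean(xj), sd = sd(xj),
               skewness = unname(shape["skewness"]),
               kurtosis = unname(shape["kurtosis"]),
               item_rest = cor(xj, rest))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("descriptives_table", "data.frame")
  out
}

#' Goldbricker screening for redundant item pairs
#'
#' For every item pair whose absolute correlation reaches `cor_min`, the
#' pair's correlation profiles with the remaining items are compared:
#' for each third item k, the dependent correlations r(i,k) and r(j,k)
#' (sharing variable k) are tested for equality with Steiger's
#' back-transformed-z method.  A pair is flagged as a redundancy
#' candidate when the proportion of significantly different correlations
#' falls below `prop_threshold` — the two items then relate to the rest
#' of the network in an indistinguishable way.
#'
#' @param data an [ordinal_panel()], or a correlation matrix when `n` is
#'   supplied (useful for printed fixtures).
#' @param alpha significance level of each dependent-correlation test.
#' @param prop_threshold pairs with a smaller proportion of significant
#'   differences are flagged.
#' @param cor_min minimum absolute pair correlation to consider.
#' @param n sample size; required when `data` is a correlation matrix.
#' @param cor_method correlation type used on raw responses.
#' @return data frame of class `redundancy_report`: one row per screened
#'   pair with its correlation, the proportion of significant
#'   differences, and the redundancy flag.  Attributes record the
#'   settings.
#' @export
goldbricker <- function(data, alpha = 0.01, prop_threshold = 0.25,
                        cor_min = 0.50, n = NULL,
                        cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  if (inherits(data, "ordinal_panel")) {
    n <- nrow(data$responses)
    R <- cor(data$responses, method = cor_method)
  } else {
    R <- as.matrix(data)
    check_symmetric(R, 1e-8, "correlation matrix")
    if (is.null(n)) stop("n must be supplied with a correlation matrix")
  }
  if (n < 30) stop("Goldbricker requires n >= 30 (got ", n, ")")
  p <- ncol(R)
  labels <- colnames(R) %||% paste0("V", seq_len(p))
  rows <- list()
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (abs(R[i, j]) < cor_min) next
      ks <- setdiff(seq_len(p), c(i, j))
      pv <- vapply(ks, function(k)
        steiger_dependent_test(R[i, k], R[j, k], R[i, j], n), numeric(1))
      prop <- mean(pv < alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(item_i = labels[i], item_j = labels[j],
                   correlation = R[i, j],
                   prop_significant = prop,
                   redundant = prop < prop_threshold)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item_i = character(), item_j = character(),
               correlation = numeric(), prop_significant = numeric(),
               redundant = logical())
  rownames(out) <- NULL
  attr(out, "settings") <- list(alpha = alpha,
                                prop_threshold = prop_threshold,
                                cor_min = cor_min, n = n,
                                cor_method = cor_method,
                                note = paste("alpha and prop_threshold are",
                                             "conventional defaults"))
  class(out) <- c("redundancy_report", "data.frame")
  out
}

#' Steiger's test for two dependent overlapping correlations
#'
#' Tests r(i,k) = r(j,k) when both correlations share variable k, using
#' Fisher z transforms and the back-transformed average correlation in
#' the covariance term.
#'
#' @param r_ik,r_jk the two correlations being compared.
#' @param r_ij correlation between the two non-shared variables.
#' @param n sample size.
#' @return two-sided p-value.
#' @export
steiger_dependent_test <- function(r_ik, r_jk, r_ij, n) {
  if (n < 4) stop("n too small for the dependent-correlation z test")
  clamp <- function(r) max(min(r, 1 - 1e-12), -1 + 1e-12)
  z1 <- atanh(clamp(r_ik)); z2 <- atanh(clamp(r_jk))
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_ij * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ij^2)
  sbar <- psi / (1 - rbar^2)^2
  denom <- sqrt(max(2 - 2 * sbar, .Machine$double.eps))
  z <- sqrt(n - 3) * (z1 - z2) / denom
  2 * pnorm(-abs(z))
}

#' Nonparanormal (rank-Gaussianizing) transform
#'
#' Each column is replaced by normal scores of its mid-ranks: with r the
#' mid-rank of an observation among n, the score is
#' `qnorm(r / (n + 1))`, Winsorized at
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))` and `1 - delta_n`, then
#' centered and scaled to unit variance.  Ties (pervasive in ordinal
#' data) share mid-ranks, so the transform is monotone and idempotent on
#' ranks.
#'
#' @param data an [ordinal_panel()] or a numeric matrix.
#' @return numeric matrix of class `gaussian_scores` with attribute
#'   `source` describing the input.
#' @export
nonparanormal_transform <- function(data) {
  if (inherits(data, "ordinal_panel")) {
    x <- data$responses
    src <- paste0("ordinal_panel:", data$wave_id)
  } else {
    x <- as.matrix(data)
    src <- "matrix"
  }
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows")
  sds <- apply(x, 2, function(col) max(col) - min(col))
  if (any(sds == 0))
    stop("zero-variance column(s); cannot Gaussianize: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  z <- npn_transform_cpp(x * 1.0, delta)
  dimnames(z) <- dimnames(x)
  structure(z, class = c("gaussian_scores", "matrix", "array"),
            source = src)
}

#' Write descriptives / redundancy report to CSV
#' @param x a `descriptives_table` or `redundancy_report`.
#' @param path output file.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
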