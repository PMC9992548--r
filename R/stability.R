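#' Nonparametric bootstrap of edge weights
#'
#' Resamples participants with replacement, re-runs the full
#' [estimate_network()] pipeline (including penalty reselection) on each
#' replicate, and summarizes every edge by its bootstrap mean and
#' percentile confidence interval.
#'
#' @param data an [ordinal_panel()].
#' @param n_boot number of bootstrap replicates (0 gives an empty
#'   report).
#' @param seed integer seed.
#' @param config a [net_config()].
#' @param level confidence level of the percentile interval.
#' @return data frame of class `edge_bootstrap` with one row per edge:
#'   sample estimate, bootstrap mean, lower and upper limits.  The
#'   attribute `n_failed` counts replicates whose estimation failed and
#'   were dropped.
#' @export
edge_bootstrap <- function(data, n_boot = 500L, seed = 1L,
                           config = net_config(), level = 0.95) {
  stopifnot(inherits(data, "ordinal_panel"))
  n <- nrow(data$responses)
  if (n < 50) stop("edge bootstrap requires n >= 50")
  full <- estimate_network(data, config)
  labels <- data$item_labels
  pair_idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  base <- data.frame(item_i = labels[pair_idx[, 1]],
                     item_j = labels[pair_idx[, 2]],
                     estimate = upper_tri(full$weights))
  if (n_boot == 0) {
    out <- cbind(base, boot_mean = NA_real_, lower = NA_real_,
                 upper = NA_real_)[integer(0), ]
    attr(out, "n_failed") <- 0L
    class(out) <- c("edge_bootstrap", "data.frame")
    return(out)
  }
  set.seed(derive_seed(seed, 21L))
  boot_seeds <- sample.int(2147483000L, n_boot)
  reps <- matrix(NA_real_, n_boot, nrow(base))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n, n, replace = TRUE)
    cfg <- config; cfg$seed <- boot_seeds[b]
    net <- tryCatch(
      estimate_network(ordinal_panel(data$responses[rows, , drop = FALSE],
                                     labels, data$community_labels,
                                     n_categories = data$n_categories),
                       cfg),
      error = function(e) NULL)
    if (is.null(net)) { n_failed <- n_failed + 1L; next }
    reps[b, ] <- upper_tri(net$weights)
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  a <- (1 - level) / 2
  out <- cbind(base,
               boot_mean = colMeans(reps),
               lower = apply(reps, 2, quantile, probs = a),
               upper = apply(reps, 2, quantile, probs = 1 - a))
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  class(out) <- c("edge_bootstrap", "data.frame")
  out
}

#' Case-dropping correlation-stability (CS) coefficient
#'
#' For each drop proportion q in `props`, repeatedly subsamples
#' `(1 - q) n` participants without replacement, re-estimates the
#' network, and correlates the statistic vector (edge weights or
#' one-step expected influence) with the full-sample vector.  The CS
#' coefficient is the largest q at which at least `quantile_level` of
#' the replicates correlate at or above `cor_threshold` with the
#' full-sample statistic (0 if none); replicates with an undefined
#' correlation count as unstable.
#'
#' @param data an [ordinal_panel()].
#' @param statistic `"edge"` or `"EI1"`.
#' @param n_boot subsample replicates per proportion.
#' @param seed integer seed.
#' @param config a [net_config()].
#' @param props drop proportions tested.
#' @param cor_threshold required correlation with the full sample.
#' @param quantile_level required fraction of replicates above the
#'   threshold.
#' @return object of class `cs_result`: the `cs` coefficient, the
#'   per-proportion table of correlation summaries, and settings.
#' @export
case_dropping_cs <- function(data, statistic = c("edge", "EI1"),
                             n_boot = 100L, seed = 1L,
                             config = net_config(),
                             props = seq(0.05, 0.75, by = 0.05),
                             cor_threshold = 0.7,
                             quantile_level = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(data, "ordinal_panel"))
  n <- nrow(data$responses)
  if (n < 100) stop("case-dropping analysis requires n >= 100")
  stat_of <- function(net) {
    if (statistic == "edge") upper_tri(net$weights)
    else unname(expected_influence(net, 1))
  }
  full_stat <- stat_of(estimate_network(data, config))
  set.seed(derive_seed(seed, 31L))
  sub_seeds <- matrix(sample.int(2147483000L, length(props) * n_boot),
                      length(props), n_boot)
  tab <- data.frame(prop = props, n_sub = NA_integer_,
                    prop_stable = NA_real_, mean_cor = NA_real_)
  for (qi in seq_along(props)) {
    m <- floor((1 - props[qi]) * n)
    cors <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(n, m)
      cfg <- config; cfg$seed <- sub_seeds[qi, b]
      net <- tryCatch(
        estimate_network(ordinal_panel(data$responses[rows, , drop = FALSE],
                                       data$item_labels,
                                       data$community_labels,
                                       n_categories = data$n_categories),
                         cfg),
        error = function(e) NULL)
      if (is.null(net)) return(NA_real_)
      s <- stat_of(net)
      if (sd(s) == 0 || sd(full_stat) == 0) return(NA_real_)
      cor(s, full_stat)
    }, numeric(1))
    tab$n_sub[qi] <- m
    tab$prop_stable[qi] <- mean(!is.na(cors) & cors >= cor_threshold)
    tab$mean_cor[qi] <- mean(cors, na.rm = TRUE)
  }
  ok <- which(tab$prop_stable >= quantile_level)
  cs <- if (length(ok) == 0) 0 else max(props[ok])
  structure(list(cs = cs, statistic = statistic, table = tab,
                 n_boot = as.integer(n_boot),
                 cor_threshold = cor_threshold,
                 quantile_level = quantile_level,
                 seed = as.integer(seed)),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat("Correlation-stability coefficient (", x$statistic, "): CS = ",
      x$cs, "\n", sep = "")
  invisible(x)
}
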