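#' Fit a cross-lagged panel network by lasso regression
#'
#' Each wave-2 item is regressed on all wave-1 items (itself included,
#' giving the autoregressive path) with an L1 penalty, which shrinks
#' small paths to exactly zero.  Both waves are nonparanormal-transformed
#' and standardized first, so coefficients are standardized.  For every
#' outcome the penalty runs over a log-spaced sequence of `n_lambda`
#' values (from the smallest penalty zeroing all coefficients down to
#' `1e-4` times it) and the value with the lowest k-fold
#' cross-validation error is selected; fold assignment is drawn once
#' from `seed` and shared across outcomes.
#'
#' @param pair a `panel_pair` ([simulate_panel()] / [read_panel_csv()])
#'   with identical participants in both waves.
#' @param n_lambda length of the penalty sequence.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @param lambda_min_ratio smallest / largest penalty.
#' @param thresh coordinate-descent convergence threshold of the inner
#'   lasso solver (tight default so retained zeros are exact).
#' @return object of class `clpn_model`: `beta` (p x p matrix,
#'   `beta[s, t]` = standardized coefficient of T1 item s predicting T2
#'   item t, autoregressive paths on the diagonal), per-outcome selected
#'   `lambda`, `in_prediction`, `out_prediction`, the transformed
#'   `scores`, and settings.
#' @export
fit_clpn <- function(pair, n_lambda = 100L, cv_folds = 10L, seed = 1L,
                     lambda_min_ratio = 1e-4, thresh = 1e-12) {
  stopifnot(inherits(pair, "panel_pair"))
  if (nrow(pair$T1$responses) != nrow(pair$T2$responses))
    stop("waves are not paired: different numbers of participants")
  if (!identical(pair$T1$item_labels, pair$T2$item_labels))
    stop("waves must measure the same items")
  p <- length(pair$T1$item_labels)
  n <- nrow(pair$T1$responses)
  if (n < 10 * p)
    warning("n < 10 p; cross-lagged estimates may be unstable")
  x1 <- scale(nonparanormal_transform(pair$T1))
  x2 <- scale(nonparanormal_transform(pair$T2))
  # run every outcome over the full penalty sequence: the default path
  # truncation would stop early for near-perfectly predicted items
  old_ctl <- glmnet::glmnet.control()
  on.exit(glmnet::glmnet.control(fdev = old_ctl$fdev,
                                 devmax = old_ctl$devmax), add = TRUE)
  glmnet::glmnet.control(fdev = 0, devmax = 1)
  set.seed(derive_seed(seed, 11L))
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))
  beta <- matrix(0, p, p,
                 dimnames = list(pair$T1$item_labels,
                                 pair$T2$item_labels))
  lambda_sel <- numeric(p)
  for (t in seq_len(p)) {
    cv <- glmnet::cv.glmnet(x1, x2[, t], family = "gaussian",
                            nlambda = n_lambda,
                            lambda.min.ratio = lambda_min_ratio,
                            foldid = foldid, standardize = FALSE,
                            intercept = FALSE, thresh = thresh)
    beta[, t] <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    lambda_sel[t] <- cv$lambda.min
  }
  model <- structure(
    list(beta = beta, lambda = stats::setNames(lambda_sel,
                                               pair$T2$item_labels),
         cv_folds = as.integer(cv_folds), n_lambda = as.integer(n_lambda),
         seed = as.integer(seed), n = n,
         item_labels = pair$T1$item_labels,
         community_labels = pair$T1$community_labels,
         scores = list(T1 = x1, T2 = x2)),
    class = "clpn_model")
  model$in_prediction <- in_prediction(model)
  model$out_prediction <- out_prediction(model)
  model
}

#' Nodewise in-prediction of a cross-lagged panel network
#'
#' The proportion of variance in each T2 item explained by the full set
#' of T1 items through the selected model: the squared correlation
#' between the model's linear predictor and the standardized observed
#' scores (0 when the node has no incoming paths).
#'
#' @param model a [fit_clpn()] result.
#' @return named numeric vector in `[0, 1]`.
#' @export
in_prediction <- function(model) {
  stopifnot(inherits(model, "clpn_model"))
  pred <- model$scores$T1 %*% model$beta
  obs <- model$scores$T2
  r2 <- vapply(seq_len(ncol(pred)), function(t) {
    if (sd(pred[, t]) == 0) return(0)
    cor(pred[, t], obs[, t])^2
  }, numeric(1))
  stats::setNames(r2, model$item_labels)
}

#' Nodewise out-prediction of a cross-lagged panel network
#'
#' The sum of squared outgoing standardized cross-lagged coefficients of
#' each T1 item; the autoregressive (diagonal) path is excluded by
#' default so the statistic captures influence on *other* symptoms.
#'
#' @param model a [fit_clpn()] result.
#' @param include_auto include the autoregressive path in the sum.
#' @return named numeric vector (>= 0).
#' @export
out_prediction <- function(model, include_auto = FALSE) {
  stopifnot(inherits(model, "clpn_model"))
  b2 <- model$beta^2
  if (!include_auto) diag(b2) <- 0
  stats::setNames(rowSums(b2), model$item_labels)
}

#' @export
print.clpn_model <- function(x, ...) {
  np <- sum(x$beta != 0)
  cat("Cross-lagged panel network:", length(x$item_labels),
      "items,", np, "retained paths (",
      sum(diag(x$beta) != 0), "autoregressive )\n")
  cat("  max in-prediction:",
      names(which.max(x$in_prediction)),
      signif(max(x$in_prediction), 3), "| max out-prediction:",
      names(which.max(x$out_prediction)),
      signif(max(x$out_prediction), 3), "\n")
  invisible(x)
}

#' Maximum-likelihood fit of a fixed cross-lagged path structure
#'
#' Refits the selected path structure without penalty and evaluates
#' standard structural-equation fit indices.  Model: T1 covariances
#' saturated, each T2 item regressed on its retained T1 predictors
#' (others fixed at zero), T2 residuals uncorrelated.  The ML estimates
#' are the equation-wise least-squares fits on the retained supports;
#' the discrepancy is `F = log|Sigma| - log|S| + tr(S Sigma^-1) - 2p`,
#' with `chi^2 = (n - 1) F`.
#'
#' `chi^2` is compared with the independence baseline (all covariances
#' zero) for CFI and TLI; `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`;
#' SRMR is the root mean squared standardized residual of the fitted
#' covariance.  When the baseline chi-square does not exceed its degrees
#' of freedom, CFI is reported as 1 by convention.
#'
#' @param model a [fit_clpn()] result (its nonzero `beta` entries define
#'   the structure, and its stored scores the sample covariance), or a
#'   logical p x p support matrix when `S` and `n` are given.
#' @param S optional 2p x 2p sample covariance (T1 block first) to fit
#'   against instead of the model's own scores.
#' @param n sample size accompanying `S`.
#' @return object of class `fit_indices`: `chi_square`, `df`, `CFI`,
#'   `TLI`, `RMSEA`, `SRMR`, plus baseline statistics.
#' @export
path_model_fit <- function(model, S = NULL, n = NULL) {
  if (inherits(model, "clpn_model")) {
    support <- model$beta != 0
    if (is.null(S)) {
      z <- cbind(model$scores$T1, model$scores$T2)
      S <- cov(z)
      n <- model$n
    }
  } else {
    support <- as.matrix(model)
    if (is.null(S) || is.null(n))
      stop("S and n are required with an explicit support matrix")
  }
  if (!any(support)) stop("the model retains no paths")
  p <- ncol(support)
  stopifnot(ncol(S) == 2 * p)
  check_symmetric(S, 1e-8, "sample covariance")
  if (!is_pos_def(S)) stop("sample covariance is not positive definite")
  path_fit_ml(S, support, n)
}

path_fit_ml <- function(S, support, n) {
  p <- ncol(support)
  S11 <- S[1:p, 1:p]
  B <- matrix(0, p, p)
  psi <- numeric(p)
  for (t in seq_len(p)) {
    idx <- which(support[, t])
    ytt <- S[p + t, p + t]
    if (length(idx) > 0) {
      b <- solve(S11[idx, idx, drop = FALSE], S[idx, p + t])
      B[idx, t] <- b
      psi[t] <- ytt - 2 * sum(b * S[idx, p + t]) +
        as.numeric(t(b) %*% S11[idx, idx] %*% b)
    } else {
      psi[t] <- ytt
    }
  }
  sigma <- rbind(cbind(S11, S11 %*% B),
                 cbind(t(B) %*% S11, t(B) %*% S11 %*% B + diag(psi, p)))
  fml <- function(sig) {
    as.numeric(determinant(sig)$modulus) -
      as.numeric(determinant(S)$modulus) +
      sum(diag(S %*% solve(sig))) - 2 * p
  }
  q <- sum(support)
  chi2 <- (n - 1) * fml(sigma)
  df <- p * (2 * p + 1) - (p * (p + 1) / 2 + q + p)
  sigma_b <- diag(diag(S))
  chi2_b <- (n - 1) * fml(sigma_b)
  df_b <- p * (2 * p + 1) - 2 * p
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  tli <- if (chi2_b / df_b <= 1) 1 else
    ((chi2_b / df_b) - (chi2 / max(df, 1))) / ((chi2_b / df_b) - 1)
  rmsea <- if (df <= 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  dsd <- sqrt(diag(S))
  resid_std <- (S - sigma) / tcrossprod(dsd)
  srmr <- sqrt(mean(resid_std[lower.tri(resid_std, diag = TRUE)]^2))
  structure(list(chi_square = chi2, df = df,
                 chi_square_baseline = chi2_b, df_baseline = df_b,
                 CFI = cfi, TLI = min(tli, 1), RMSEA = rmsea, SRMR = srmr,
                 n = n, n_paths = q, B = B, psi = psi,
                 implied = sigma),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "Path model fit: chi2(%d) = %.2f | CFI = %.3f TLI = %.3f RMSEA = %.3f SRMR = %.3f\n",
    x$df, x$chi_square, x$CFI, x$TLI, x$RMSEA, x$SRMR))
  invisible(x)
}
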