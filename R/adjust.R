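## Embedding reduction and covariate balancing for the continuous treatment.
## The balancing engine is entropy balancing: minimize the entropy divergence
## from uniform weights subject to exact first-order balance (zero weighted
## treatment-covariate covariance, preserved means). This targets the same
## balance conditions as non-parametric CBPS for continuous treatments, but
## as a strictly convex program with a unique, reproducible solution.

#' Fit PCA on training-split embeddings
#'
#' Centered on train means only; components are ordered by explained
#' variance. `k_model` defaults to the smallest k whose cumulative explained
#' variance reaches `var_target`.
#'
#' @param phi_train n x d matrix of train-split embeddings (n >= 9).
#' @param k_model number of components used as covariates in the mediation
#'   models (default 3), or `"auto"` for the explained-variance rule.
#' @param k_balance number of components for the balancing model.
#' @param var_target cumulative explained-variance target for auto mode.
#' @return object of class `pca_model` with loadings, explained-variance
#'   ratios, centering means, `k_model` and `k_balance`.
#' @export
fit_pca <- function(phi_train, k_model = 3, k_balance = 6, var_target = 0.90) {
  if (nrow(phi_train) < 9) stopf("need at least 9 training embeddings for PCA")
  pc <- stats::prcomp(phi_train, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- pc$sdev > 1e-10 * pc$sdev[1]
  if (!all(keep)) warnf("rank-deficient embeddings: %d components returned", sum(keep))
  k_auto <- which(cumsum(evr) >= var_target)[1]
  structure(list(loadings = pc$rotation[, keep, drop = FALSE],
                 evr = evr[keep], center = pc$center,
                 k_model = if (identical(k_model, "auto")) min(k_auto, sum(keep))
                           else min(k_model, sum(keep)),
                 k_balance = min(k_balance, sum(keep))),
            class = "pca_model")
}

#' Project embeddings onto fitted principal components
#'
#' Applies the train-split centering to any split.
#'
#' @param pca a `pca_model`.
#' @param phi n x d embedding matrix.
#' @param k number of components (default: all fitted).
#' @return n x k score matrix.
#' @export
pca_transform <- function(pca, phi, k = ncol(pca$loadings)) {
  sc <- sweep(phi, 2, pca$center) %*% pca$loadings[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, k_model = %d, k_balance = %d\n",
              ncol(x$loadings), x$k_model, x$k_balance))
  cat("explained variance:", paste0(round(100 * x$evr, 1), "%", collapse = " "), "\n")
  invisible(x)
}

## entropy-balancing dual objective: w_i prop exp(lambda' g_i), all balance
## targets are zero after internal standardization
eb_dual <- function(lambda, G) {
  eta <- as.numeric(G %*% lambda)
  m <- max(eta)
  log(mean(exp(eta - m))) + m
}

eb_dual_grad <- function(lambda, G) {
  eta <- as.numeric(G %*% lambda)
  w <- exp(eta - max(eta))
  w <- w / sum(w)
  as.numeric(crossprod(G, w))
}

#' Estimate covariate-balancing weights for a continuous treatment
#'
#' Solves the entropy-balancing convex program: minimize the entropy
#' divergence from uniform weights subject to mean(w) = 1, preserved weighted
#' means of the (standardized) treatment and covariates, and zero weighted
#' covariance between treatment and every covariate. Balance diagnostics
#' (weighted/unweighted correlations, Kish effective sample size, weight
#' distribution summary) are computed on the weighted sample.
#'
#' @param Z treatment vector (carbohydrate grams).
#' @param covariates numeric matrix or data frame (for the analysis of meal
#'   windows: the leading principal components, meal-time glucose, and a
#'   cohort indicator).
#' @param tol maximum tolerated absolute constraint residual.
#' @return object of class `weight_set`: weights `w` (mean 1), diagnostics
#'   (per-covariate correlation with Z before/after, mean absolute
#'   correlation reduction, `n_eff`, weight summary), and the solved dual.
#' @export
estimate_weights <- function(Z, covariates, tol = 1e-6) {
  X <- as.matrix(covariates)
  n <- length(Z)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (n <= ncol(X) + 2) stopf("need n > %d observations for %d covariates",
                              ncol(X) + 2, ncol(X))
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  zs <- std(Z)
  Xs <- apply(X, 2, std)
  keep <- apply(Xs, 2, function(c) stats::sd(c) > 0)
  Xs <- Xs[, keep, drop = FALSE]
  ## balance features, all with target zero under the weighted measure:
  ## the standardized first moments of Z and X (already mean zero) and the
  ## Z-X cross moments (zero weighted covariance)
  G <- cbind(z = zs, Xs, Xs * zs)
  colnames(G) <- c("Z", colnames(Xs), paste0("Z:", colnames(Xs)))

  fit <- stats::optim(rep(0, ncol(G)), eb_dual, eb_dual_grad, G = G,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  w <- exp(as.numeric(G %*% fit$par))
  w <- w * (n / sum(w))
  resid <- abs(colSums(w * G) / n)
  if (max(resid) > tol) {
    fit <- stats::optim(fit$par, eb_dual, eb_dual_grad, G = G, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-16))
    w <- exp(as.numeric(G %*% fit$par))
    w <- w * (n / sum(w))
    resid <- abs(colSums(w * G) / n)
    if (max(resid) > 100 * tol)
      stopf("balance constraints infeasible; worst covariate: %s (residual %.2e)",
            colnames(G)[which.max(resid)], max(resid))
  }

  wcor <- function(x, y, w) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    sxy <- sum(w * (x - mx) * (y - my))
    sxx <- sum(w * (x - mx)^2); syy <- sum(w * (y - my)^2)
    if (sxx <= 0 || syy <= 0) return(0)
    sxy / sqrt(sxx * syy)
  }
  cor_before <- apply(X[, keep, drop = FALSE], 2, function(x)
    suppressWarnings(stats::cor(Z, x)))
  cor_before[!is.finite(cor_before)] <- 0
  cor_after <- apply(X[, keep, drop = FALSE], 2, function(x) wcor(Z, x, w))
  mac_before <- mean(abs(cor_before))
  mac_after <- mean(abs(cor_after))
  structure(list(
    w = w,
    diagnostics = list(
      covariate = colnames(X)[keep],
      cor_before = cor_before, cor_after = cor_after,
      mean_abs_cor_before = mac_before, mean_abs_cor_after = mac_after,
      pct_reduction = if (mac_before > 0) 100 * (1 - mac_after / mac_before) else 0,
      n_eff = kish_ess(w), n = n,
      weight_summary = c(median = stats::median(w),
                         iqr_lo = unname(stats::quantile(w, 0.25)),
                         iqr_hi = unname(stats::quantile(w, 0.75)),
                         frac_gt_2 = mean(w > 2)),
      max_resid = max(resid)),
    dual = fit$par), class = "weight_set")
}

#' Kish effective sample size
#'
#' @param w weight vector.
#' @return `(sum w)^2 / sum(w^2)`; equals `length(w)` for uniform weights.
#' @export
kish_ess <- function(w) sum(w)^2 / sum(w^2)

#' @export
print.weight_set <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("weight_set: n = %d, n_eff = %.1f (%.1f%%)\n", d$n, d$n_eff,
              100 * d$n_eff / d$n))
  cat(sprintf("mean |corr(Z, X)|: %.4f -> %.4f (%.1f%% reduction)\n",
              d$mean_abs_cor_before, d$mean_abs_cor_after, d$pct_reduction))
  ws <- d$weight_summary
  cat(sprintf("weights: median %.3f, IQR [%.2f, %.2f], %.1f%% > 2.0\n",
              ws["median"], ws["iqr_lo"], ws["iqr_hi"], 100 * ws["frac_gt_2"]))
  invisible(x)
}

#' Balance report table
#'
#' Per-covariate before/after correlations with the treatment plus three
#' summary rows (mean absolute correlation with percent reduction, Kish
#' effective sample size, weight-distribution summary).
#'
#' @param weight_set a fitted `weight_set`.
#' @param path optional CSV path to write the report to.
#' @return data frame with `length(covariates) + 3` rows.
#' @export
balance_report <- function(weight_set, path = NULL) {
  d <- weight_set$diagnostics
  ws <- d$weight_summary
  tab <- data.frame(
    quantity = c(paste0("corr_Z_", d$covariate), "mean_abs_corr", "n_eff",
                 "weight_median"),
    before = c(d$cor_before, d$mean_abs_cor_before, d$n, 1),
    after = c(d$cor_after, d$mean_abs_cor_after, d$n_eff, ws[["median"]]),
    note = c(rep("", length(d$covariate)),
             sprintf("%.1f%% reduction", d$pct_reduction),
             sprintf("%.1f%% of n", 100 * d$n_eff / d$n),
             sprintf("IQR [%.2f, %.2f], %.1f%% > 2", ws[["iqr_lo"]],
                     ws[["iqr_hi"]], 100 * ws[["frac_gt_2"]])),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
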