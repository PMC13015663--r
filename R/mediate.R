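## Mediation machinery: left-censored Tobit mediator model, mixed-effects and
## quantile outcome models, and the quasi-Bayesian Monte Carlo decomposition
## of the treatment effect into ACME (through insulin), ADE, and total
## effect.

#' Fit the left-censored Tobit mediator model
#'
#' Weighted maximum likelihood for a Gaussian linear model of the latent
#' bolus demand, left-censored at zero: censored observations contribute the
#' normal CDF, uncensored ones the density. Backed by
#' [survival::survreg()]; the returned covariance (observed information) is
#' on the scale of `(coefficients, log sigma)`.
#'
#' @param M mediator vector (bolus units, >= 0; exact zeros are censored).
#' @param Z treatment vector.
#' @param X covariate matrix (principal components).
#' @param w observation weights (mean 1); default uniform.
#' @return object of class `tobit_fit`.
#' @export
fit_tobit <- function(M, Z, X, w = NULL) {
  n <- length(M)
  w <- w %||% rep(1, n)
  if (any(w < 0)) stopf("weights must be >= 0")
  if (any(M < 0)) stopf("mediator must be >= 0 (left-censored at 0)")
  if (all(M <= 0)) stopf("all observations censored; Tobit model unidentified")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  dat <- data.frame(.M = M, .Z = Z, X, .w = w, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.M, .M > 0, type = 'left') ~ .Z +",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::survreg(fml, data = dat, weights = .w, dist = "gaussian")
  if (is.na(fit$scale) || fit$scale <= 0)
    stopf("Tobit fit failed to converge (scale %.3g)", fit$scale)
  co <- fit$coefficients
  names(co) <- c("(Intercept)", "Z", colnames(X))
  V <- fit$var  # covariance of (coefficients, log sigma)
  structure(list(coef = co, sigma = fit$scale, vcov = V,
                 censor_point = 0, n = n, n_censored = sum(M <= 0),
                 X = X, Z = Z, w = w, loglik = fit$loglik[2]),
            class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("tobit_fit: n = %d (%d censored at 0), sigma = %.3f\n",
              x$n, x$n_censored, x$sigma))
  print(round(x$coef, 4))
  invisible(x)
}

#' Fit the mixed-effects outcome model
#'
#' Weighted linear mixed model of the glucose excursion on treatment,
#' mediator and covariates with a random intercept per subject
#' ([lme4::lmer()]). When the random-intercept variance is singular or there
#' are too few repeated subjects, the model is refit as weighted least
#' squares and flagged.
#'
#' @param y outcome vector (Delta-G at one horizon, mg/dL).
#' @param Z treatment vector.
#' @param M mediator vector.
#' @param X covariate matrix.
#' @param subject subject identifier vector.
#' @param w observation weights (mean 1).
#' @return object of class `outcome_fit` (kind `"mixed"`), with fixed-effect
#'   coefficients and their covariance (conditional on the variance
#'   components), the random-intercept SD and residual SD.
#' @export
fit_outcome_mixed <- function(y, Z, M, X, subject, w = NULL) {
  n <- length(y)
  w <- w %||% rep(1, n)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  dat <- data.frame(.y = y, .Z = Z, .M = M, X, .subject = subject,
                    .w = w, check.names = FALSE)
  xterms <- paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  singular <- FALSE
  tab <- table(subject)
  enough <- sum(tab >= 2) >= 2
  fit <- NULL
  if (enough) {
    fml <- stats::as.formula(paste(".y ~ .Z + .M +", xterms, "+ (1 | .subject)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, weights = .w, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    singular <- lme4::isSingular(fit, tol = 1e-6)
  }
  if (!enough || singular) {
    lfml <- stats::as.formula(paste(".y ~ .Z + .M +", xterms))
    lfit <- stats::lm(lfml, data = dat, weights = .w)
    co <- stats::coef(lfit)
    V <- stats::vcov(lfit)
    re_sd <- 0
    res_sd <- summary(lfit)$sigma
  } else {
    co <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    re_sd <- attr(vc$.subject, "stddev")[[1]]
    res_sd <- attr(vc, "sc")
  }
  names(co) <- c("(Intercept)", "Z", "M", colnames(X))
  structure(list(kind = "mixed", tau = NA_real_, coef = co, vcov = V,
                 re_sd = unname(re_sd), resid_sd = unname(res_sd),
                 singular = singular || !enough,
                 X = X, Z = Z, M = M, w = w, n = n),
            class = "outcome_fit")
}

## weighted quantile (type-7-like interpolation on the weighted CDF)
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  stats::approx(cw, x, xout = p, rule = 2)$y
}

## smoothed check loss rho_tau and gradient; eps -> 0 recovers the exact loss
check_loss_smooth <- function(beta, D, y, w, tau, eps) {
  u <- y - as.numeric(D %*% beta)
  ## tau*u + eps*log(1 + exp(-u/eps)), computed stably (-> -u as u -> -Inf)
  v <- -u / eps
  soft <- ifelse(v > 30, -u, eps * log1p(exp(pmin(v, 30))))
  sum(w * (tau * u + soft))
}

check_loss_grad <- function(beta, D, y, w, tau, eps) {
  u <- y - as.numeric(D %*% beta)
  s <- 1 / (1 + exp(pmin(700, u / eps)))   # sigma(-u/eps)
  -as.numeric(crossprod(D, w * (tau - s)))
}

#' Fit a weighted quantile-regression outcome model
#'
#' Minimizes the weighted check loss at quantile `tau` (smoothed-loss BFGS
#' with epsilon continuation, started at weighted least squares). The
#' coefficient covariance is a Powell-type sandwich with a Hall-Sheather
#' bandwidth; a pairs bootstrap is available instead.
#'
#' @param y outcome vector.
#' @param Z treatment vector.
#' @param M mediator vector.
#' @param X covariate matrix.
#' @param tau quantile level in (0, 1).
#' @param w observation weights (mean 1).
#' @param se `"asymptotic"` (kernel sandwich) or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `se = "bootstrap"`.
#' @return object of class `outcome_fit` (kind `"quantile"`).
#' @export
fit_outcome_quantile <- function(y, Z, M, X, tau = 0.5, w = NULL,
                                 se = c("asymptotic", "bootstrap"), n_boot = 200) {
  se <- match.arg(se)
  if (tau <= 0 || tau >= 1) stopf("tau must be in (0, 1)")
  n <- length(y)
  w <- w %||% rep(1, n)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  D <- cbind(`(Intercept)` = 1, Z = Z, M = M, X)
  p <- ncol(D)
  if (n <= 10 * p) stopf("need n > 10 x %d coefficients for quantile regression", p)
  qrd <- qr(D)
  if (qrd$rank < p)
    stopf("degenerate design; collinear columns: %s",
          paste(colnames(D)[qrd$pivot[(qrd$rank + 1):p]], collapse = ", "))
  beta <- qr.coef(qr(sqrt(w) * D), sqrt(w) * y)
  scale0 <- stats::sd(y - as.numeric(D %*% beta))
  for (eps in scale0 * c(0.5, 0.1, 0.02, 0.004, 5e-4)) {
    opt <- stats::optim(beta, check_loss_smooth, check_loss_grad, D = D, y = y,
                        w = w, tau = tau, eps = eps, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-12))
    beta <- opt$par
  }
  r <- y - as.numeric(D %*% beta)

  if (se == "asymptotic") {
    ## Hall-Sheather bandwidth in tau-space; sparsity by difference quotient
    z975 <- stats::qnorm(0.975)
    qt <- stats::qnorm(tau)
    h <- n^(-1/3) * z975^(2/3) *
      ((1.5 * stats::dnorm(qt)^2) / (2 * qt^2 + 1))^(1/3)
    lo <- max(tau - h, 1e-3); hi <- min(tau + h, 1 - 1e-3)
    spars <- (weighted_quantile(r, w, hi) - weighted_quantile(r, w, lo)) / (hi - lo)
    spars <- max(spars, 1e-8)
    A <- crossprod(D, (w / spars) * D)
    B <- tau * (1 - tau) * crossprod(D, w^2 * D)
    Ainv <- solve(A)
    V <- Ainv %*% B %*% Ainv
  } else {
    bs <- matrix(NA_real_, n_boot, p)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bb <- qr.coef(qr(sqrt(w[idx]) * D[idx, , drop = FALSE]), sqrt(w[idx]) * y[idx])
      for (eps in scale0 * c(0.1, 0.02, 0.004)) {
        bb <- stats::optim(bb, check_loss_smooth, check_loss_grad,
                           D = D[idx, , drop = FALSE], y = y[idx], w = w[idx],
                           tau = tau, eps = eps, method = "BFGS",
                           control = list(maxit = 200))$par
      }
      bs[b, ] <- bb
    }
    V <- stats::cov(bs)
  }
  dimnames(V) <- list(colnames(D), colnames(D))
  structure(list(kind = "quantile", tau = tau, coef = stats::setNames(beta, colnames(D)),
                 vcov = V, X = X, Z = Z, M = M, w = w, n = n, se = se),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("outcome_fit (%s%s): n = %d\n", x$kind,
              if (x$kind == "quantile") sprintf(", tau = %.2f", x$tau) else "",
              x$n))
  print(round(x$coef, 4))
  invisible(x)
}

#' Quasi-Bayesian mediation decomposition
#'
#' Samples mediator and outcome coefficients from their asymptotic normal
#' distributions; per draw, simulates potential mediators `M(z)` by drawing
#' the latent Gaussian at each treatment anchor (common noise across
#' anchors) and censoring at zero, evaluates the outcome linear predictor at
#' the four `(z, M(z'))` combinations, and averages over observations
#' (weighted) and over both treatment anchors. Point estimates are means
#' over draws, intervals are 2.5/97.5 percentiles, and the two-sided Monte
#' Carlo p-value is floored at `1/n_sims`. For no-interaction outcome models
#' the identity `TE = ACME + ADE` holds exactly for every draw.
#'
#' @param med_fit a `tobit_fit`.
#' @param out_fit an `outcome_fit` sharing the same covariates.
#' @param z0 baseline treatment anchor (scalar or per-observation vector).
#' @param z1 shifted anchor, typically `z0 + dose`.
#' @param n_sims Monte Carlo draws.
#' @param seed integer seed.
#' @param include_draws keep the per-draw effects (attribute `draws`).
#' @return object of class `mediation_result`: data frame with one row per
#'   effect (ACME, ADE, TE) and columns estimate, ci_lo, ci_hi, p, n_sims,
#'   n_obs.
#' @export
mediate_decompose <- function(med_fit, out_fit, z0, z1, n_sims = 1000,
                              seed = 1L, include_draws = FALSE) {
  X <- med_fit$X
  if (!identical(dim(X), dim(out_fit$X)) ||
      !isTRUE(all.equal(unname(X), unname(out_fit$X))))
    stopf("mediator and outcome models must share the same covariate set")
  n <- nrow(X)
  z0 <- rep_len(z0, n)
  z1 <- rep_len(z1, n)
  wobs <- med_fit$w / sum(med_fit$w)
  set.seed(as.integer(seed))

  thM <- MASS::mvrnorm(n_sims, c(med_fit$coef, `Log(scale)` = log(med_fit$sigma)),
                       med_fit$vcov)
  thY <- MASS::mvrnorm(n_sims, out_fit$coef, out_fit$vcov)
  pX <- ncol(X)
  aX <- thM[, 2 + seq_len(pX), drop = FALSE]        # mediator covariate coefs
  sig <- exp(thM[, pX + 3])
  ## latent mediator location, n x S
  baseM <- X %*% t(aX)
  eps <- matrix(stats::rnorm(n * n_sims), n, n_sims)
  lat0 <- sweep(baseM + eps * rep(sig, each = n), 2, thM[, 1], "+") +
    outer(z0, thM[, 2])
  lat1 <- sweep(baseM + eps * rep(sig, each = n), 2, thM[, 1], "+") +
    outer(z1, thM[, 2])
  M0 <- pmax(0, lat0)
  M1 <- pmax(0, lat1)

  cY0 <- thY[, 1]; cZ <- thY[, 2]; cM <- thY[, 3]
  bXY <- thY[, 3 + seq_len(pX), drop = FALSE]
  baseY <- X %*% t(bXY)                              # n x S
  ybar <- function(zv, Mm) {
    ## weighted observation average of the outcome linear predictor, per sim
    lp <- sweep(baseY + Mm * rep(cM, each = n), 2, cY0, "+") +
      outer(zv, cZ)
    as.numeric(crossprod(wobs, lp))
  }
  y11 <- ybar(z1, M1); y10 <- ybar(z1, M0)
  y01 <- ybar(z0, M1); y00 <- ybar(z0, M0)
  acme <- 0.5 * ((y11 - y10) + (y01 - y00))
  te <- y11 - y00
  ## algebraically identical to averaging the two anchor-conditioned direct
  ## effects; this form keeps TE = ACME + ADE exact in floating point
  ade <- te - acme

  summarize <- function(d) {
    ci <- unname(stats::quantile(d, c(0.025, 0.975)))
    ## two-sided MC p; >=/<= so that identically-zero draws give p = 1
    p <- max(2 * min(mean(d >= 0), mean(d <= 0)), 1 / n_sims)
    c(estimate = mean(d), ci_lo = ci[1], ci_hi = ci[2], p = min(p, 1))
  }
  tab <- as.data.frame(rbind(ACME = summarize(acme), ADE = summarize(ade),
                             TE = summarize(te)))
  tab <- cbind(effect = rownames(tab), tab, n_sims = n_sims, n_obs = n)
  rownames(tab) <- NULL
  class(tab) <- c("mediation_result", "data.frame")
  if (include_draws) attr(tab, "draws") <- cbind(acme = acme, ade = ade, te = te)
  tab
}

#' @export
print.mediation_result <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$estimate <- round(y$estimate, 2)
  y$ci_lo <- round(y$ci_lo, 2)
  y$ci_hi <- round(y$ci_hi, 2)
  y$p <- format_p(y$p)
  print(y)
  invisible(x)
}

#' Stratified mediation analysis over horizons, doses and outcome models
#'
#' Runs the full factorial of (stratum x horizon x dose x outcome model)
#' mediation decompositions on the test split: one Tobit mediator fit per
#' stratum, one outcome fit per (stratum, horizon, model), one decomposition
#' per dose, with per-cell seeds derived from the global seed. Treatment
#' anchors are the train-split meal-type medians; pooled strata use
#' per-observation anchors so each meal is contrasted against its own
#' meal-type median.
#'
#' @param mw a split `meal_windows` object.
#' @param X_test covariate matrix for test-split windows (rows align with
#'   `mw$meta[mw$meta$split == "test", ]`).
#' @param w weights for test-split windows (mean 1).
#' @param anchors anchor table from [meal_type_anchors()].
#' @param strata subset of `c("pooled", "breakfast", "lunch", "dinner",
#'   "snack")`.
#' @param horizons outcome horizons (minutes).
#' @param doses dose contrasts (grams).
#' @param models subset of `c("mixed", "q25", "q50", "q75")`.
#' @param n_sims Monte Carlo draws per decomposition.
#' @param seed global seed.
#' @param min_stratum_n strata with fewer test windows are skipped with a
#'   warning.
#' @return data frame with columns stratum, model, tau, horizon_min, dose_g,
#'   effect, estimate, ci_lo, ci_hi, p, n_sims, n_obs.
#' @export
run_stratified <- function(mw, X_test, w, anchors,
                           strata = c("pooled", "breakfast", "lunch", "dinner", "snack"),
                           horizons = HORIZONS, doses = c(15, 30, 45),
                           models = c("mixed", "q25", "q50", "q75"),
                           n_sims = 1000, seed = 1L, min_stratum_n = 30) {
  meta <- mw$meta[mw$meta$split == "test", ]
  stopifnot(nrow(meta) == nrow(X_test), nrow(meta) == length(w))
  taus <- c(q25 = 0.25, q50 = 0.50, q75 = 0.75)
  rows <- list()
  cell <- 0L
  for (st in strata) {
    sel <- if (st == "pooled") rep(TRUE, nrow(meta)) else meta$meal_type == st
    nst <- sum(sel)
    if (nst < min_stratum_n) {
      warnf("stratum %s has %d test windows (< %d); skipped", st, nst, min_stratum_n)
      next
    }
    ms <- meta[sel, ]
    Xs <- X_test[sel, , drop = FALSE]
    ws <- w[sel]
    ws <- ws / mean(ws)
    z0 <- anchors$z0[match(ms$meal_type, anchors$meal_type)]
    if (anyNA(z0)) stopf("missing anchor for a meal type in stratum %s", st)
    med_fit <- fit_tobit(ms$M, ms$Z, Xs, ws)
    for (hz in horizons) {
      y <- ms[[paste0("dg_", hz)]]
      for (md in models) {
        out_fit <- tryCatch(
          if (md == "mixed")
            fit_outcome_mixed(y, ms$Z, ms$M, Xs, ms$subject_id, ws)
          else
            fit_outcome_quantile(y, ms$Z, ms$M, Xs, tau = taus[[md]], w = ws),
          error = function(e) {
            warnf("stratum %s, horizon %d, model %s skipped: %s",
                  st, hz, md, conditionMessage(e))
            NULL
          })
        if (is.null(out_fit)) next
        for (dg in doses) {
          cell <- cell + 1L
          res <- mediate_decompose(med_fit, out_fit, z0, z0 + dg,
                                   n_sims = n_sims,
                                   seed = derive_seed(seed, 100 + cell))
          res <- cbind(stratum = st, model = md,
                       tau = if (md == "mixed") NA_real_ else taus[[md]],
                       horizon_min = hz, dose_g = dg, res)
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
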