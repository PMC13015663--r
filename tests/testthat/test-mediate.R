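## Small independent oracles: a direct optim() MLE for the censored
## likelihood, and exhaustive basis search for quantile regression.

tobit_loglik <- function(par, M, Z, X, w) {
  beta <- par[-length(par)]
  sigma <- exp(par[length(par)])
  xb <- as.numeric(cbind(1, Z, X) %*% beta)
  cens <- M <= 0
  sum(w[cens] * stats::pnorm(0, xb[cens], sigma, log.p = TRUE)) +
    sum(w[!cens] * stats::dnorm(M[!cens], xb[!cens], sigma, log = TRUE))
}

test_that("Tobit matches a direct censored-likelihood MLE and recovers truth", {
  set.seed(11)
  n <- 2000
  Z <- rnorm(n, 50, 20)
  X <- matrix(rnorm(n * 3), n)
  M <- pmax(0, -1.6 + 0.1 * Z + as.numeric(X %*% c(0.5, -0.4, 0.3)) + rnorm(n, 0, 2))
  expect_gt(mean(M == 0), 0.08)
  w <- runif(n, 0.5, 1.5); w <- w / mean(w)
  tf <- fit_tobit(M, Z, X, w)
  expect_lt(abs(tf$coef[["Z"]] - 0.1), 3 * sqrt(tf$vcov[2, 2]))
  ## independent oracle: direct likelihood maximization
  opt <- optim(unname(c(tf$coef * 0, 0)), tobit_loglik, M = M, Z = Z, X = X,
               w = w, method = "BFGS", control = list(fnscale = -1, maxit = 500))
  expect_equal(unname(tf$coef), opt$par[1:5], tolerance = 1e-3)
  expect_equal(unname(tf$sigma), exp(opt$par[6]), tolerance = 1e-3)
  expect_equal(tf$n_censored, sum(M == 0))
})

test_that("Tobit without censoring equals weighted least squares", {
  set.seed(12)
  n <- 800
  Z <- rnorm(n, 50, 15)
  X <- matrix(rnorm(n * 2), n)
  M <- 30 + 0.1 * Z + as.numeric(X %*% c(0.4, -0.2)) + rnorm(n, 0, 2)
  w <- runif(n, 0.5, 1.5); w <- w / mean(w)
  tf <- fit_tobit(M, Z, X, w)
  wls <- lm(M ~ Z + X, weights = w)
  expect_lt(max(abs(tf$coef - coef(wls))), 1e-6)
  ## one exact zero is treated as censored
  M2 <- M; M2[1] <- 0
  tf2 <- fit_tobit(M2, Z, X, w)
  expect_equal(tf2$n_censored, 1L)
  expect_error(fit_tobit(rep(0, 10), rnorm(10), matrix(rnorm(10))), "censored")
  expect_error(fit_tobit(c(-1, 1), 1:2, matrix(1:2)), ">= 0")
})

test_that("mixed outcome model handles degenerate and informative subject effects", {
  set.seed(13)
  n_sub <- 50; per <- 20
  n <- n_sub * per
  subj <- rep(sprintf("S%02d", 1:n_sub), each = per)
  Z <- rnorm(n, 50, 15); M <- 0.1 * Z + rnorm(n, 0, 2)
  X <- matrix(rnorm(n * 2), n)
  ## zero subject variance: fixed effects match plain weighted regression
  y0 <- 5 + 0.3 * Z - 2 * M + as.numeric(X %*% c(2, -1)) + rnorm(n, 0, 8)
  f0 <- fit_outcome_mixed(y0, Z, M, X, subj)
  l0 <- lm(y0 ~ Z + M + X)
  expect_lt(max(abs(f0$coef - coef(l0))), 0.05)
  expect_lt(f0$re_sd, 2)
  ## subject SD 15 recovered
  b <- rep(rnorm(n_sub, 0, 15), each = per)
  y1 <- y0 + b
  f1 <- fit_outcome_mixed(y1, Z, M, X, subj)
  expect_lt(abs(f1$re_sd - 15), 3 * 15 / sqrt(2 * (n_sub - 1)))
  ## adding a constant shifts only the intercept
  f2 <- fit_outcome_mixed(y1 + 100, Z, M, X, subj)
  expect_equal(f2$coef[["(Intercept)"]] - f1$coef[["(Intercept)"]], 100,
               tolerance = 1e-6)
  expect_equal(f2$coef[-1], f1$coef[-1], tolerance = 1e-6)
})

test_that("quantile regression matches an exhaustive small-instance oracle", {
  set.seed(14)
  n <- 41
  x <- rnorm(n)
  y <- 1 + 2 * x + rt(n, 3)
  D <- cbind(1, x)
  tau <- 0.5
  ## oracle: a QR solution interpolates p = 2 observations; enumerate pairs
  best <- Inf; bbest <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    b <- tryCatch(solve(D[c(i, j), ], y[c(i, j)]), error = function(e) NULL)
    if (is.null(b)) next
    r <- y - D %*% b
    loss <- sum(r * (tau - (r < 0)))
    if (loss < best) { best <- loss; bbest <- b }
  }
  ## the smoothed-loss machinery on the same (intercept, x) design
  D2 <- cbind(`(Intercept)` = 1, Z = x)
  b0 <- qr.coef(qr(D2), y)
  for (eps in sd(y) * c(0.5, 0.1, 0.02, 0.004, 5e-4))
    b0 <- optim(b0, glycomediate:::check_loss_smooth, glycomediate:::check_loss_grad,
                D = D2, y = y, w = rep(1, n), tau = tau, eps = eps,
                method = "BFGS", control = list(maxit = 400, reltol = 1e-12))$par
  expect_equal(unname(b0), unname(bbest), tolerance = 1e-2)
})

test_that("quantile slopes are flat under location shift and ordered under scale shift", {
  set.seed(15)
  n <- 3000
  Z <- rnorm(n, 50, 15); M <- 0.1 * Z + rnorm(n, 0, 2)
  X <- matrix(rnorm(n * 2), n)
  y_loc <- 5 + 0.4 * Z - 2 * M + as.numeric(X %*% c(2, -1)) + rnorm(n, 0, 10)
  fits <- lapply(c(0.25, 0.5, 0.75), function(tau)
    fit_outcome_quantile(y_loc, Z, M, X, tau = tau))
  sl <- sapply(fits, function(f) f$coef[["Z"]])
  se <- sapply(fits, function(f) sqrt(f$vcov["Z", "Z"]))
  expect_lt(abs(sl[1] - sl[3]), 3 * sqrt(se[1]^2 + se[3]^2))
  ## median slope close to the mean-model slope under symmetric noise
  lm_sl <- coef(lm(y_loc ~ Z + M + X))[["Z"]]
  expect_lt(abs(sl[2] - lm_sl), 3 * se[2])
  ## multiplicative scale heterogeneity: slope increases with tau
  y_sc <- 5 + 0.4 * Z - 2 * M + as.numeric(X %*% c(2, -1)) +
    (1 + 0.02 * Z) * rnorm(n, 0, 10)
  sl_sc <- sapply(c(0.25, 0.5, 0.75), function(tau)
    fit_outcome_quantile(y_sc, Z, M, X, tau = tau)$coef[["Z"]])
  expect_true(all(diff(sl_sc) > 0))
  expect_error(fit_outcome_quantile(y_loc[1:30], Z[1:30], M[1:30], X[1:30, ],
                                    tau = 0.5),
               "coefficients")
  expect_error(fit_outcome_quantile(y_loc, Z, M, cbind(X, X[, 1]), tau = 0.5),
               "collinear")
  expect_error(fit_outcome_quantile(y_loc, Z, M, X, tau = 1.2), "tau")
})

test_that("bootstrap and asymptotic QR covariances broadly agree", {
  set.seed(16)
  n <- 400
  Z <- rnorm(n, 50, 15); M <- 0.1 * Z + rnorm(n, 0, 2)
  X <- matrix(rnorm(n), n)
  y <- 5 + 0.4 * Z - 2 * M + 2 * X[, 1] + rnorm(n, 0, 10)
  fa <- fit_outcome_quantile(y, Z, M, X, tau = 0.5, se = "asymptotic")
  fb <- fit_outcome_quantile(y, Z, M, X, tau = 0.5, se = "bootstrap", n_boot = 120)
  ratio <- sqrt(diag(fb$vcov)) / sqrt(diag(fa$vcov))
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("decomposition reproduces the product-of-coefficients closed form", {
  set.seed(17)
  ## uncensored linear-linear system: alpha1 = 0.1, beta1 = 0.3, beta2 = -2
  n <- 2000
  X <- matrix(rnorm(n * 3), n); colnames(X) <- paste0("PC", 1:3)
  Z <- rnorm(n, 50, 15)
  M <- 30 + 0.1 * Z + as.numeric(X %*% c(0.4, -0.3, 0.2)) + rnorm(n, 0, 2)
  subj <- rep(sprintf("S%02d", 1:20), each = 100)
  b <- rep(rnorm(20, 0, 5), each = 100)
  y <- 10 + 0.3 * Z - 2 * M + as.numeric(X %*% c(3, 2, -2)) + b + rnorm(n, 0, 8)
  tf <- fit_tobit(M, Z, X)
  of <- fit_outcome_mixed(y, Z, M, X, subj)
  res <- mediate_decompose(tf, of, z0 = 50, z1 = 80, n_sims = 1000, seed = 2,
                           include_draws = TRUE)
  dr <- attr(res, "draws")
  expect_lt(abs(res$estimate[res$effect == "ACME"] + 6), 3 * sd(dr[, "acme"]))
  expect_lt(abs(res$estimate[res$effect == "ADE"] - 9), 3 * sd(dr[, "ade"]))
  ## decomposition identity holds exactly per draw
  expect_equal(max(abs(dr[, "te"] - dr[, "acme"] - dr[, "ade"])), 0)
  ## CI ordering and p-value range
  expect_true(all(res$ci_lo <= res$estimate & res$estimate <= res$ci_hi))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("severing the mediator path zeroes ACME; covariate mismatch is rejected", {
  set.seed(18)
  n <- 500
  X <- matrix(rnorm(n * 2), n); colnames(X) <- paste0("PC", 1:2)
  Z <- rnorm(n, 50, 15)
  M <- 30 + 0.1 * Z + rnorm(n, 0, 2)
  y <- 10 + 0.3 * Z - 2 * M + rnorm(n, 0, 8)
  tf <- fit_tobit(M, Z, X)
  of <- fit_outcome_mixed(y, Z, M, X, rep(sprintf("S%d", 1:10), each = 50))
  tf0 <- tf
  tf0$coef["Z"] <- 0
  tf0$vcov[2, ] <- 0; tf0$vcov[, 2] <- 0
  r0 <- mediate_decompose(tf0, of, 50, 80, n_sims = 400, seed = 3,
                          include_draws = TRUE)
  expect_lt(max(abs(attr(r0, "draws")[, "acme"])), 1e-6)
  expect_gt(r0$p[r0$effect == "ACME"], 0.9)
  tf_bad <- fit_tobit(M, Z, X[, 1, drop = FALSE])
  expect_error(mediate_decompose(tf_bad, of, 50, 80), "covariate")
})

test_that("stratified runner produces the factorial table, seeded and dose-linear", {
  set.seed(19)
  cfg <- generator_config(
    mediator_coeffs = list(alpha0 = 50, alpha1 = 0.1, alpha2 = rep(0.5, 4),
                           sigma_m = 2))
  s <- structural_sample(cfg, 900, seed = 4, n_subjects = 12)
  ## wrap the tabular draws as a minimal meal_windows test split
  mw <- structure(list(meta = cbind(s, data.frame(split = "test", G0 = 150,
                                                  meal_time = seq_len(nrow(s)),
                                                  day = 1))), class = "meal_windows")
  mw$meta$split[1:100] <- "train"
  X <- as.matrix(s[s$Z > -Inf, paste0("U", 1:3)])[mw$meta$split == "test", ]
  colnames(X) <- paste0("PC", 1:3)
  anchors <- data.frame(meal_type = cfg$meal_types$meal_type,
                        z0 = cfg$meal_types$carb_mean)
  n_test <- sum(mw$meta$split == "test")
  tab <- run_stratified(mw, X, rep(1, n_test), anchors, strata = "pooled",
                        doses = c(15, 30, 45), models = c("mixed", "q50"),
                        n_sims = 200, seed = 5)
  expect_equal(nrow(tab), 6 * 3 * 2 * 3)
  tab2 <- run_stratified(mw, X, rep(1, n_test), anchors, strata = "pooled",
                         doses = c(15, 30, 45), models = c("mixed", "q50"),
                         n_sims = 200, seed = 5)
  expect_identical(tab, tab2)
  ## ACME scales ~ 1:2:3 in dose for the uncensored linear generator
  a <- tab[tab$effect == "ACME" & tab$model == "mixed" & tab$horizon_min == 120, ]
  a <- a[order(a$dose_g), ]
  width <- (a$ci_hi - a$ci_lo) / (2 * 1.96)
  expect_lt(abs(a$estimate[2] - 2 * a$estimate[1]), 3 * sqrt(sum(width^2)))
  expect_lt(abs(a$estimate[3] - 3 * a$estimate[1]), 3 * sqrt(sum(width^2)))
  ## small strata are skipped with a warning
  expect_warning(
    run_stratified(mw, X, rep(1, n_test), anchors, strata = "snack",
                   min_stratum_n = 1e6),
    "skipped")
})
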