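## Gradient checks compare the analytic backward pass against central
## differences on a tiny network; penalty examples are hand-computed.

test_that("analytic gradients match central differences on the full loss", {
  set.seed(42)
  ## bal/lin/ci hold batch-level statistics fixed within a step
  ## (stop-gradient); the fully differentiable terms are checked here and
  ## the stop-gradient ones in the next block
  cfg <- tiny_clae_config(penalty_weights = c(bal = 0, lin = 0, ci = 0, stab = 0.01))
  n <- 8
  X <- array(rnorm(n * 24 * 5), c(n, 24, 5))
  batch <- list(X = X, X_clean = X, Z = rnorm(n), M = matrix(rnorm(n)),
                Y = matrix(rnorm(n * 6), n))
  p <- glycomediate:::clae_init(cfg)
  p$gW2 <- matrix(rnorm(length(p$gW2), 0, 0.3), nrow(p$gW2))
  half <- rep(c(TRUE, FALSE), 4)
  fwd <- glycomediate:::clae_loss_fwd(p, batch, cfg, NULL, half)
  ga <- glycomediate:::flatten_params(glycomediate:::clae_loss_bwd(p, fwd, cfg))
  v0 <- glycomediate:::flatten_params(p)
  f <- function(v) glycomediate:::clae_loss_fwd(
    glycomediate:::unflatten_params(v, p), batch, cfg, NULL, half)$total
  idx <- sort(sample(length(v0), 80))
  gn <- vapply(idx, function(j) {
    e <- rep(0, length(v0)); e[j] <- 1e-5
    (f(v0 + e) - f(v0 - e)) / 2e-5
  }, 0)
  expect_lt(max(abs(ga[idx] - gn)), 1e-6)
})

test_that("stop-gradient penalties match numeric gradients at fixed coefficients", {
  set.seed(7)
  n <- 12; d <- 4
  psi <- matrix(rnorm(n * d), n)
  Z <- rnorm(n); M <- 0.5 * Z + rnorm(n)
  res <- glycomediate:::ci_penalty_grad(psi, Z, M)
  W <- cbind(1, psi)
  bZ <- qr.coef(qr(W), Z); bM <- qr.coef(qr(W), M)
  ffix <- function(ps) {
    Wf <- cbind(1, ps)
    eZ <- Z - as.numeric(Wf %*% bZ); eM <- M - as.numeric(Wf %*% bM)
    (sum(eZ * eM) / sqrt(sum(eZ^2) * sum(eM^2)))^2
  }
  gn <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d)) {
    e <- matrix(0, n, d); e[i, j] <- 1e-6
    gn[i, j] <- (ffix(psi + e) - ffix(psi - e)) / 2e-6
  }
  expect_lt(max(abs(res$dpsi - gn)), 1e-7)

  ## whitened balancing mean term with the pooled covariance held fixed
  Zb <- c(rnorm(6), rnorm(6) + 1)
  bal <- glycomediate:::balancing_penalty_grad(psi[1:12, ], Zb)
  S <- cov(psi[1:12, ]) + diag(1e-2, d)
  fbal <- function(ps) {
    hi <- Zb > median(Zb)
    A <- ps[hi, , drop = FALSE]; B <- ps[!hi, , drop = FALSE]
    delta <- colMeans(A) - colMeans(B)
    sum(delta * solve(S, delta)) + sum((cov(A) - cov(B))^2)
  }
  gnb <- matrix(0, 12, d)
  for (i in 1:12) for (j in 1:d) {
    e <- matrix(0, 12, d); e[i, j] <- 1e-6
    gnb[i, j] <- (fbal(psi[1:12, ] + e) - fbal(psi[1:12, ] - e)) / 2e-6
  }
  expect_lt(max(abs(bal$dpsi - gnb)), 1e-6)

  pred <- matrix(rnorm(n * 6), n); phi <- matrix(rnorm(n * 3), n)
  Yt <- matrix(rnorm(n * 6), n)
  lp <- glycomediate:::lin_penalty_grad(pred, phi, Yt)
  B <- qr.coef(qr(cbind(1, phi)), Yt)
  flin <- function(pr, ph) mean((pr - cbind(1, ph) %*% B)^2)
  gn2 <- matrix(0, n, 3)
  for (i in seq_len(n)) for (j in seq_len(3)) {
    e <- matrix(0, n, 3); e[i, j] <- 1e-6
    gn2[i, j] <- (flin(pred, phi + e) - flin(pred, phi - e)) / 2e-6
  }
  expect_lt(max(abs(lp$dphi - gn2)), 1e-7)
})

test_that("balancing penalty is zero on matched moments and d^2 on a mean shift", {
  set.seed(1)
  base <- matrix(rnorm(8), 4, 2)
  Z <- c(1, 2, 10, 20)              # groups {1,2} vs {10,20} by median split
  psi_same <- rbind(base[1:2, ], base[1:2, ])
  expect_equal(balancing_penalty(psi_same, Z), 0)
  ## shift the high group by d in coordinate 1: penalty = d^2
  d <- 0.7
  psi_shift <- psi_same
  psi_shift[3:4, 1] <- psi_shift[3:4, 1] + d
  expect_equal(balancing_penalty(psi_shift, Z), d^2, tolerance = 1e-12)
  ## permuting samples within groups changes nothing
  expect_equal(balancing_penalty(psi_shift[c(2, 1, 4, 3), ], Z), d^2,
               tolerance = 1e-12)
  expect_true(is.na(balancing_penalty(matrix(rnorm(6), 3), c(1, 1, 5))))
  expect_gte(balancing_penalty(matrix(rnorm(40), 20), rnorm(20)), 0)
})

test_that("conditional independence penalty tracks residual Z-M association", {
  set.seed(3)
  n <- 512
  psi <- matrix(rnorm(n * 4), n)
  ## M driven by psi only -> penalty near zero
  M1 <- as.numeric(psi %*% c(1, -1, 0.5, 0.2)) + 0.05 * rnorm(n)
  Z <- rnorm(n)
  expect_lt(conditional_independence_penalty(psi, Z, M1), 0.02)
  ## M = Z exactly with psi independent of Z -> penalty near 1
  expect_gt(conditional_independence_penalty(psi, Z, Z), 0.95)
  ## duplicating every sample leaves the value unchanged
  p1 <- conditional_independence_penalty(psi, Z, M1)
  p2 <- conditional_independence_penalty(rbind(psi, psi), c(Z, Z), c(M1, M1))
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_true(conditional_independence_penalty(psi, Z, M1) >= 0)
  expect_true(conditional_independence_penalty(psi, Z, M1) <= 1)
})

test_that("loss decomposes additively and applies the configured weights", {
  set.seed(5)
  n <- 16
  X <- array(rnorm(n * 24 * 5), c(n, 24, 5))
  batch <- list(X = X, Z = rnorm(n), M = matrix(rnorm(n)),
                Y = matrix(rnorm(n * 6), n))
  cfg0 <- tiny_clae_config(l2 = 0,
                           penalty_weights = c(bal = 0, lin = 0, ci = 0, stab = 0))
  set.seed(9); p <- glycomediate:::clae_init(cfg0)
  l0 <- clae_loss(p, batch, cfg0)
  hw <- cfg0$head_weights
  expect_equal(l0$total, sum(hw * l0$terms[names(hw)]), tolerance = 1e-12)
  cfg1 <- tiny_clae_config(l2 = 0)
  l1 <- clae_loss(p, batch, cfg1)
  pw <- cfg1$penalty_weights
  expect_equal(pw[["bal"]], 2)
  expect_equal(l1$total,
               sum(hw * l1$terms[names(hw)]) + sum(pw * l1$penalties[names(pw)]),
               tolerance = 1e-12)
  expect_error(clae_loss(p, list(X = X[1:2, , , drop = FALSE], Z = rnorm(2),
                                 M = matrix(rnorm(2)), Y = matrix(rnorm(12), 2)),
                         cfg1),
               "batch size")
})

test_that("encoding is deterministic, pre-treatment only, and guarded", {
  sw <- small_windows()
  mw <- sw$mw
  cfg <- tiny_clae_config(epochs = 2)
  model <- clae_train(mw, cfg)
  e1 <- clae_encode(mw, model)
  e2 <- clae_encode(mw, model)
  expect_identical(e1$phi, e2$phi)
  expect_equal(dim(e1$phi), c(nrow(mw$meta), 8L))
  expect_true(all(is.finite(e1$phi)))
  ## identical pre-matrices give identical embeddings regardless of metadata
  Xp <- mw$pre_std[c(1, 1), , , drop = FALSE]
  ep <- clae_encode(Xp, model)
  expect_equal(ep$phi[1, ], ep$phi[2, ])
  ## perturbing post-meal outcomes cannot change the embeddings (leakage)
  mw2 <- mw
  mw2$meta$dg_120 <- mw2$meta$dg_120 + 100
  expect_identical(clae_encode(mw2, model)$phi, e1$phi)
  expect_error(clae_encode(mw$pre_std[, , 1:4, drop = FALSE], model), "5")
})

test_that("training is seeded, abortable on divergence, and a no-op at 0 epochs", {
  mw <- small_windows()$mw
  cfg <- tiny_clae_config(epochs = 2)
  m1 <- clae_train(mw, cfg)
  m2 <- clae_train(mw, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  m0 <- clae_train(mw, tiny_clae_config(epochs = 0))
  expect_null(m0$trace)
  set.seed(glycomediate:::derive_seed(1L, 31))
  p_init <- glycomediate:::clae_init(tiny_clae_config(epochs = 0))
  expect_equal(m0$params[names(p_init)], p_init)
  expect_false(isTRUE(all.equal(m1$params$pW, m0$params$pW)))
})

test_that("treatment head weight is rejected outside ablation mode", {
  expect_error(clae_config(head_weights = c(pre = 0.5, med = 0.5, out = 2,
                                            treat = 1)),
               "ablation_mode")
  cfg <- clae_config(head_weights = c(pre = 0.5, med = 0.5, out = 2, treat = 1),
                     ablation_mode = TRUE)
  expect_equal(cfg$head_weights[["treat"]], 1)
  expect_error(clae_config(penalty_weights = c(bal = -1, lin = 0, ci = 0, stab = 0)),
               ">= 0")
  expect_error(clae_config(architecture = "recurrent"), "conv")
})

test_that("balance score is 1 minus mean absolute correlation, in [0, 1]", {
  set.seed(4)
  phi <- matrix(rnorm(400), 50)
  Z <- rnorm(50)
  bs <- balance_score(phi, Z)
  expect_true(bs >= 0 && bs <= 1)
  expect_equal(bs, 1 - mean(abs(cor(phi, Z))))
  ## embeddings constructed exactly orthogonal to Z in-sample score 1
  phi_orth <- apply(phi, 2, function(c) residuals(lm(c ~ Z)))
  expect_equal(balance_score(phi_orth, Z), 1, tolerance = 1e-10)
})

test_that("ablation grid trains per (configuration, seed) and selects by rule", {
  mw <- small_windows()$mw
  grid <- list(all = c(bal = 2, lin = 0.1, ci = 0.05, stab = 0.01),
               balancing_only = c(bal = 2, lin = 0, ci = 0, stab = 0),
               none = c(bal = 0, lin = 0, ci = 0, stab = 0))
  tab <- clae_ablation(mw, grid, seeds = 1:2, base_config = tiny_clae_config(epochs = 1))
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$configuration), names(grid))
  expect_error(clae_ablation(mw, grid[1], seeds = 1), "configurations")
  ## selection: maximize balance subject to outcome R2 threshold
  fake <- data.frame(configuration = rep(c("a", "b"), each = 2), seed = c(1, 2),
                     outcome_r2 = c(0.4, 0.4, 0.2, 0.2),
                     balance = c(0.5, 0.5, 0.9, 0.9))
  expect_equal(select_encoder(fake, r2_threshold = 0.3), "a")
  expect_equal(select_encoder(fake, r2_threshold = 0), "b")
  expect_error(select_encoder(fake, r2_threshold = 0.9), "threshold")
})
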