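## Causally-constrained autoencoder (convolutional encoder, multi-head
## reconstruction, four causal penalties). The encoder compresses the
## 24 x 5 standardized pre-meal channel matrix into an 8-dimensional
## pre-treatment embedding phi; a learned nonlinear basis expansion with a
## residual connection, psi = phi + g(phi), feeds the penalties.

#' Encoder configuration
#'
#' Defaults are the selected model configuration: three convolutional blocks
#' (32, 64, 128 filters, kernel 3, max pooling stride 2, global average
#' pooling), latent dimension 8, outcome head weight 2.0 over pre-treatment
#' and mediator heads (0.5 each), a zero-weight treatment head, penalty
#' weights (balancing 2.0, linearizability 0.1, conditional independence
#' 0.05, stability 0.01), RMSprop at lr 1e-3, 100 epochs, batch 32, gradient
#' clipping at norm 1, input noise SD 0.05, dropout 0.2, L2 1e-4.
#'
#' @param architecture only `"conv"` is provided.
#' @param latent_dim embedding dimension.
#' @param conv_filters filter depths of the three blocks.
#' @param hidden_basis width of the basis-expansion hidden layer (the
#'   decoder heads themselves are linear maps from phi, true to the linear
#'   autoencoder design).
#' @param l2 L2 penalty on weight matrices (added to the loss).
#' @param dropout dropout rate on the pooled feature vector during training.
#' @param input_noise_sd SD of Gaussian noise added to standardized inputs
#'   during training.
#' @param head_weights named vector (pre, med, out, treat). The treatment
#'   head must stay at zero unless `ablation_mode = TRUE`: a positive weight
#'   trains the encoder to predict treatment, which conflicts with balancing.
#' @param penalty_weights named vector (bal, lin, ci, stab).
#' @param optimizer `"rmsprop"` (selected) or `"adamw"`.
#' @param lr,weight_decay,epochs,batch_size,grad_clip training settings.
#' @param ablation_mode allow a positive treatment-head weight.
#' @param seed integer seed controlling initialization, shuffling, noise and
#'   dropout.
#' @return list of class `clae_config`.
#' @export
clae_config <- function(architecture = "conv", latent_dim = 8,
                        conv_filters = c(32, 64, 128), hidden_basis = 16,
                        l2 = 1e-4, dropout = 0.2,
                        input_noise_sd = 0.05,
                        head_weights = c(pre = 0.5, med = 0.5, out = 2, treat = 0),
                        penalty_weights = c(bal = 2, lin = 0.1, ci = 0.05, stab = 0.01),
                        optimizer = "rmsprop", lr = 1e-3, weight_decay = 1e-5,
                        epochs = 100, batch_size = 32, grad_clip = 1,
                        ablation_mode = FALSE, seed = 1L) {
  if (!identical(architecture, "conv"))
    stopf("only the convolutional encoder is provided (architecture = 'conv')")
  if (latent_dim < 1) stopf("latent_dim must be >= 1")
  if (any(c(head_weights, penalty_weights) < 0))
    stopf("head and penalty weights must be >= 0")
  if (head_weights[["treat"]] > 0 && !ablation_mode)
    stopf("the treatment head weight must be 0 unless ablation_mode = TRUE")
  structure(list(architecture = architecture, latent_dim = as.integer(latent_dim),
                 conv_filters = conv_filters, hidden_basis = hidden_basis,
                 l2 = l2, dropout = dropout,
                 input_noise_sd = input_noise_sd, head_weights = head_weights,
                 penalty_weights = penalty_weights, optimizer = optimizer,
                 lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 ablation_mode = ablation_mode, seed = as.integer(seed)),
            class = "clae_config")
}

clae_init <- function(config, n_channels = 5, n_steps = 24) {
  k <- 3
  f <- config$conv_filters
  d <- config$latent_dim
  hb <- config$hidden_basis
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  n_feat <- f[3] + n_channels
  p <- list(
    c1W = he(k * n_channels, k * n_channels, f[1]), c1b = rep(0, f[1]),
    c2W = he(k * f[1], k * f[1], f[2]), c2b = rep(0, f[2]),
    c3W = he(k * f[2], k * f[2], f[3]), c3b = rep(0, f[3]),
    pW = he(n_feat, n_feat, d), pb = rep(0, d),
    gW1 = he(d, d, hb), gb1 = rep(0, hb),
    gW2 = matrix(0, hb, d), gb2 = rep(0, d),     # g starts at zero: psi = phi
    preW = he(d, d, n_steps * n_channels), preb = rep(0, n_steps * n_channels),
    medW = he(d, d, 1), medb = 0,
    outW = he(d, d, 6), outb = rep(0, 6),
    trW = he(d, d, 1), trb = 0
  )
  p
}

## encoder forward pass: standardized input array [n, 24, 5] -> phi [n, d]
encoder_fwd <- function(p, X, drop_mask = NULL) {
  n <- dim(X)[1]
  c1 <- conv1d_fwd(X, p$c1W, p$c1b); r1 <- relu_fwd(c1$out); p1 <- pool2_fwd(r1$out)
  c2 <- conv1d_fwd(p1$out, p$c2W, p$c2b); r2 <- relu_fwd(c2$out); p2 <- pool2_fwd(r2$out)
  c3 <- conv1d_fwd(p2$out, p$c3W, p$c3b); r3 <- relu_fwd(c3$out)
  gp <- gap_fwd(r3$out)
  tmean <- gap_fwd(X)                      # per-channel temporal means
  feat <- cbind(gp, tmean)
  featd <- if (is.null(drop_mask)) feat else feat * drop_mask
  phi <- dense_fwd(featd, p$pW, p$pb)
  list(phi = phi, cache = list(X = X, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                               p2 = p2, c3 = c3, r3 = r3, feat = feat,
                               featd = featd, drop_mask = drop_mask, n = n))
}

encoder_bwd <- function(p, dphi, cache) {
  g <- list()
  db <- dense_bwd(dphi, cache$featd, p$pW)
  g$pW <- db$dW; g$pb <- db$db
  dfeat <- db$dX
  if (!is.null(cache$drop_mask)) dfeat <- dfeat * cache$drop_mask
  nf <- ncol(cache$feat)
  dgp <- dfeat[, seq_len(nf - 5), drop = FALSE]
  dtmean <- dfeat[, nf - 5 + 1:5, drop = FALSE]
  d3 <- dim(cache$r3$out)
  dA <- gap_bwd(dgp, d3) * cache$r3$mask
  cb <- conv1d_bwd(dA, cache$c3$X2, p$c3W, dim(cache$p2$out))
  g$c3W <- cb$dW; g$c3b <- cb$db
  dA <- pool2_bwd(cb$dA, cache$p2$first, dim(cache$r2$out)) * cache$r2$mask
  cb <- conv1d_bwd(dA, cache$c2$X2, p$c2W, dim(cache$p1$out))
  g$c2W <- cb$dW; g$c2b <- cb$db
  dA <- pool2_bwd(cb$dA, cache$p1$first, dim(cache$r1$out)) * cache$r1$mask
  cb <- conv1d_bwd(dA, cache$c1$X2, p$c1W, dim(cache$X))
  g$c1W <- cb$dW; g$c1b <- cb$db
  ## dtmean also flows into X, but X is data; nothing to accumulate
  g
}

#' Moment-matching balancing penalty
#'
#' Squared Euclidean distance between group mean embeddings plus squared
#' Frobenius distance between group covariance matrices, where groups are
#' meals with treatment above versus at-or-below the batch median. Zero iff
#' the first two moments coincide.
#'
#' @param psi n x d matrix of (basis-expanded) embeddings.
#' @param Z treatment vector.
#' @return non-negative scalar; `NA` when either group has fewer than two
#'   members (the training loop skips the penalty and counts the event).
#' @export
balancing_penalty <- function(psi, Z) {
  hi <- Z > stats::median(Z)
  if (sum(hi) < 2 || sum(!hi) < 2) return(NA_real_)
  m1 <- colMeans(psi[hi, , drop = FALSE]); m0 <- colMeans(psi[!hi, , drop = FALSE])
  C1 <- stats::cov(psi[hi, , drop = FALSE]); C0 <- stats::cov(psi[!hi, , drop = FALSE])
  sum((m1 - m0)^2) + sum((C1 - C0)^2)
}

## training-time variant: the mean-difference term uses the Mahalanobis
## metric of the pooled batch covariance (held fixed within the step, like
## the regression coefficients of the other penalties). Coordinate-wise mean
## matching is blind to treatment-predictive directions hidden in correlated
## coordinates; the whitened form penalizes any linearly predictive
## direction.
balancing_penalty_grad <- function(psi, Z, whiten = TRUE) {
  hi <- Z > stats::median(Z)
  d <- ncol(psi)
  dpsi <- matrix(0, nrow(psi), d)
  if (sum(hi) < 2 || sum(!hi) < 2) return(list(value = NA_real_, dpsi = dpsi))
  A <- psi[hi, , drop = FALSE]; B <- psi[!hi, , drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  CA <- stats::cov(A); CB <- stats::cov(B)
  D <- CA - CB
  delta <- mA - mB
  if (whiten) {
    S <- stats::cov(psi) + diag(1e-2, d)
    Sid <- solve(S, delta)                 # S is stop-gradient
    mean_term <- sum(delta * Sid)
    dm <- 2 * Sid
  } else {
    mean_term <- sum(delta^2)
    dm <- 2 * delta
  }
  dpsi[hi, ] <- matrix(dm / nA, nA, d, byrow = TRUE) +
    (4 / (nA - 1)) * sweep(A, 2, mA) %*% D
  dpsi[!hi, ] <- matrix(-dm / nB, nB, d, byrow = TRUE) -
    (4 / (nB - 1)) * sweep(B, 2, mB) %*% D
  list(value = mean_term + sum(D^2), dpsi = dpsi)
}

#' Conditional-independence penalty
#'
#' Squared Pearson correlation between the residuals of treatment and of the
#' mediator after batch-level least-squares projection onto `[1, psi]`. Lies
#' in \[0, 1\]; zero when treatment and mediator are conditionally
#' uncorrelated given the embeddings.
#'
#' @param psi n x d matrix of basis-expanded embeddings.
#' @param Z treatment vector.
#' @param M mediator vector.
#' @return scalar in \[0, 1\] (0 with degenerate residual variance).
#' @export
conditional_independence_penalty <- function(psi, Z, M) {
  ci_penalty_grad(psi, Z, M)$value
}

ci_penalty_grad <- function(psi, Z, M) {
  Z <- as.numeric(Z)
  M <- as.numeric(M)
  n <- nrow(psi)
  W <- cbind(1, psi)
  dpsi <- matrix(0, n, ncol(psi))
  if (n <= ncol(W) + 1) return(list(value = 0, dpsi = dpsi, skipped = TRUE))
  qrW <- qr(W)
  bZ <- qr.coef(qrW, Z); bM <- qr.coef(qrW, M)
  bZ[is.na(bZ)] <- 0; bM[is.na(bM)] <- 0
  eZ <- Z - as.numeric(W %*% bZ)
  eM <- M - as.numeric(W %*% bM)
  Sz <- sum(eZ^2); Sm <- sum(eM^2); Szm <- sum(eZ * eM)
  if (Sz < 1e-10 || Sm < 1e-10) return(list(value = 0, dpsi = dpsi, skipped = TRUE))
  r <- Szm / sqrt(Sz * Sm)
  dZr <- eM / sqrt(Sz * Sm) - r * eZ / Sz
  dMr <- eZ / sqrt(Sz * Sm) - r * eM / Sm
  ## residual dependence on psi with projection coefficients held fixed
  dpsi <- -2 * r * (outer(dZr, bZ[-1]) + outer(dMr, bM[-1]))
  list(value = r^2, dpsi = dpsi, skipped = FALSE)
}

## linearizability: outcome head prediction vs best batch-level linear
## prediction of the outcome targets from phi (coefficients held fixed)
lin_penalty_grad <- function(pred_out, phi, Yt) {
  n <- nrow(phi)
  W <- cbind(1, phi)
  if (n <= ncol(W) + 1)
    return(list(value = 0, dpred = matrix(0, n, ncol(pred_out)),
                dphi = matrix(0, n, ncol(phi))))
  B <- qr.coef(qr(W), Yt)
  B[is.na(B)] <- 0
  lin <- W %*% B
  diff <- pred_out - lin
  k <- length(diff)
  list(value = sum(diff^2) / k,
       dpred = 2 * diff / k,
       dphi = -(2 * diff / k) %*% t(B[-1, , drop = FALSE]))
}

## stability: squared Frobenius distance between the embedding covariance
## matrices of two random batch halves
stab_penalty_grad <- function(psi, half_a) {
  d <- ncol(psi)
  dpsi <- matrix(0, nrow(psi), d)
  if (sum(half_a) < 2 || sum(!half_a) < 2) return(list(value = NA_real_, dpsi = dpsi))
  A <- psi[half_a, , drop = FALSE]; B <- psi[!half_a, , drop = FALSE]
  CA <- stats::cov(A); CB <- stats::cov(B)
  D <- CA - CB
  dpsi[half_a, ] <- (4 / (nrow(A) - 1)) * sweep(A, 2, colMeans(A)) %*% D
  dpsi[!half_a, ] <- -(4 / (nrow(B) - 1)) * sweep(B, 2, colMeans(B)) %*% D
  list(value = sum(D^2), dpsi = dpsi)
}

## batch standardization of the embeddings fed to the moment-matching
## penalties; without it the objective can shrink the embedding scale to
## lower the penalties without removing treatment information
bn_fwd <- function(psi) {
  m <- colMeans(psi)
  s <- apply(psi, 2, stats::sd)
  s[s < 1e-8] <- 1
  list(y = sweep(sweep(psi, 2, m), 2, s, "/"), s = s)
}

bn_bwd <- function(G, bn) {
  n <- nrow(G)
  y <- bn$y
  corr <- sweep(y, 2, colSums(G * y) / (n - 1), "*")
  sweep(G - matrix(colMeans(G), n, ncol(G), byrow = TRUE) - corr, 2, bn$s, "/")
}

## full forward pass + per-term loss breakdown (+ caches for the backward
## pass). `batch` carries X (inputs), X_clean (pre-head target), Z, M, Y
## (standardized targets); drop_mask/half_a are drawn by the caller.
clae_loss_fwd <- function(p, batch, config, drop_mask = NULL, half_a = NULL) {
  enc <- encoder_fwd(p, batch$X, drop_mask)
  phi <- enc$phi
  n <- nrow(phi)
  h1 <- tanh(dense_fwd(phi, p$gW1, p$gb1))
  psi <- phi + dense_fwd(h1, p$gW2, p$gb2)
  pred_pre <- dense_fwd(phi, p$preW, p$preb)
  pred_med <- dense_fwd(phi, p$medW, p$medb)
  pred_out <- dense_fwd(phi, p$outW, p$outb)
  pred_tr <- dense_fwd(phi, p$trW, p$trb)

  Xt <- matrix(batch$X_clean, n)
  hw <- config$head_weights
  pw <- config$penalty_weights
  terms <- c(pre = mean((pred_pre - Xt)^2),
             med = mean((pred_med - batch$M)^2),
             out = mean((pred_out - batch$Y)^2),
             treat = if (hw[["treat"]] > 0) mean((pred_tr - batch$Z)^2) else 0)

  if (is.null(half_a)) half_a <- rep(c(TRUE, FALSE), length.out = n)
  bn <- bn_fwd(psi)                    # scale-free moment-matching penalties
  bal <- balancing_penalty_grad(bn$y, batch$Z)
  ci <- ci_penalty_grad(psi, batch$Z, batch$M)
  lin <- lin_penalty_grad(pred_out, phi, batch$Y)
  stab <- stab_penalty_grad(bn$y, half_a)
  pen <- c(bal = if (is.na(bal$value)) 0 else bal$value,
           lin = lin$value, ci = ci$value,
           stab = if (is.na(stab$value)) 0 else stab$value)
  l2_term <- config$l2 * sum(vapply(p[grepl("W", names(p))],
                                    function(w) sum(w^2), 0))
  total <- sum(hw * terms[names(hw)]) + sum(pw * pen[names(pw)]) + l2_term
  if (!is.finite(total)) {
    bad <- c(terms, pen)[!is.finite(c(terms, pen))]
    stopf("non-finite loss term: %s", paste(names(bad), collapse = ", "))
  }
  list(total = total, terms = terms, penalties = pen, l2 = l2_term,
       skipped = c(bal = is.na(bal$value), ci = isTRUE(ci$skipped),
                   stab = is.na(stab$value)),
       cache = list(enc = enc, phi = phi, h1 = h1, psi = psi,
                    pred_pre = pred_pre, pred_med = pred_med,
                    pred_out = pred_out,
                    pred_tr = pred_tr, Xt = Xt, batch = batch,
                    bn = bn, bal = bal, ci = ci, lin = lin, stab = stab))
}

clae_loss_bwd <- function(p, fwd, config) {
  cc <- fwd$cache
  n <- nrow(cc$phi)
  hw <- config$head_weights
  pw <- config$penalty_weights
  g <- zero_like(p)

  dphi <- matrix(0, n, ncol(cc$phi))
  ## head losses
  dpre <- hw[["pre"]] * 2 * (cc$pred_pre - cc$Xt) / length(cc$Xt)
  db <- dense_bwd(dpre, cc$phi, p$preW)
  g$preW <- g$preW + db$dW; g$preb <- g$preb + db$db; dphi <- dphi + db$dX
  dmed <- hw[["med"]] * 2 * (cc$pred_med - cc$batch$M) / length(cc$batch$M)
  db <- dense_bwd(dmed, cc$phi, p$medW)
  g$medW <- g$medW + db$dW; g$medb <- g$medb + db$db; dphi <- dphi + db$dX
  dout <- hw[["out"]] * 2 * (cc$pred_out - cc$batch$Y) / length(cc$batch$Y)
  dout <- dout + pw[["lin"]] * cc$lin$dpred
  db <- dense_bwd(dout, cc$phi, p$outW)
  g$outW <- g$outW + db$dW; g$outb <- g$outb + db$db; dphi <- dphi + db$dX
  if (hw[["treat"]] > 0) {
    dtr <- hw[["treat"]] * 2 * (cc$pred_tr - cc$batch$Z) / length(cc$batch$Z)
    db <- dense_bwd(dtr, cc$phi, p$trW)
    g$trW <- g$trW + db$dW; g$trb <- g$trb + db$db; dphi <- dphi + db$dX
  }

  ## penalties acting on psi (and lin on phi directly); the moment-matching
  ## penalties act on the batch-standardized psi
  dpsi <- bn_bwd(pw[["bal"]] * cc$bal$dpsi + pw[["stab"]] * cc$stab$dpsi, cc$bn) +
    pw[["ci"]] * cc$ci$dpsi
  dphi <- dphi + pw[["lin"]] * cc$lin$dphi
  ## psi = phi + gW2' tanh(gW1' phi + b) + b2
  db <- dense_bwd(dpsi, cc$h1, p$gW2)
  g$gW2 <- g$gW2 + db$dW; g$gb2 <- g$gb2 + db$db
  dh1 <- db$dX * (1 - cc$h1^2)
  db <- dense_bwd(dh1, cc$phi, p$gW1)
  g$gW1 <- g$gW1 + db$dW; g$gb1 <- g$gb1 + db$db
  dphi <- dphi + dpsi + db$dX

  ge <- encoder_bwd(p, dphi, cc$enc$cache)
  for (nm in names(ge)) g[[nm]] <- g[[nm]] + ge[[nm]]
  ## L2 on weight matrices
  for (nm in names(p)[grepl("W", names(p))])
    g[[nm]] <- g[[nm]] + 2 * config$l2 * p[[nm]]
  g
}

#' Per-batch loss with breakdown
#'
#' Evaluates the full objective on one batch: the weighted head
#' reconstruction losses plus the four causal penalties (computed on the
#' basis-expanded embeddings) and the L2 term.
#'
#' @param params parameter list (from training or [clae_init()]).
#' @param batch list with `X` (n x 24 x 5 standardized inputs), `X_clean`
#'   (pre-head target, defaults to `X`), `Z`, `M`, `Y` (standardized
#'   targets).
#' @param config a [clae_config()].
#' @return list with `total`, `terms` (pre/med/out/treat MSEs), `penalties`
#'   (bal/lin/ci/stab), and `l2`.
#' @export
clae_loss <- function(params, batch, config) {
  if (length(batch$Z) < 4) stopf("batch size must be >= 4 for the penalties")
  batch$X_clean <- batch$X_clean %||% batch$X
  out <- clae_loss_fwd(params, batch, config)
  out$cache <- NULL
  out
}

make_clae_batch <- function(Xarr, idx, Z, M, Y) {
  list(X = Xarr[idx, , , drop = FALSE], X_clean = Xarr[idx, , , drop = FALSE],
       Z = Z[idx], M = matrix(M[idx]), Y = Y[idx, , drop = FALSE])
}

#' Train the causally-constrained autoencoder
#'
#' Runs the configured optimizer with gradient-norm clipping, input Gaussian
#' noise and dropout on the training split of a standardized `meal_windows`
#' object. Mediator, outcome and treatment targets are standardized with
#' train-split moments. Fully seeded: identical config + data give an
#' identical metrics trace.
#'
#' @param mw a split, standardized `meal_windows` object.
#' @param config a [clae_config()].
#' @return object of class `clae_model`: list with `params`, `config`,
#'   `target_scaler`, `trace` (per-epoch loss breakdown), and
#'   `skip_counts` (batches where a penalty was skipped).
#' @export
clae_train <- function(mw, config = clae_config()) {
  meta <- mw$meta
  tr <- which(meta$split == "train")
  if (!length(tr)) stopf("train split is empty")
  Xarr <- mw$pre_std[tr, , , drop = FALSE]
  sc <- function(v) {
    m <- mean(v); s <- stats::sd(v); if (!is.finite(s) || s == 0) s <- 1
    list(mean = m, sd = s)
  }
  scM <- sc(meta$M[tr]); scZ <- sc(meta$Z[tr])
  dgcols <- paste0("dg_", HORIZONS)
  Ymat <- as.matrix(meta[tr, dgcols])
  scY <- list(mean = colMeans(Ymat), sd = apply(Ymat, 2, stats::sd))
  scY$sd[scY$sd == 0] <- 1
  Zs <- (meta$Z[tr] - scZ$mean) / scZ$sd
  Ms <- (meta$M[tr] - scM$mean) / scM$sd
  Ys <- sweep(sweep(Ymat, 2, scY$mean), 2, scY$sd, "/")

  set.seed(derive_seed(config$seed, 31))
  p <- clae_init(config, n_channels = dim(Xarr)[3], n_steps = dim(Xarr)[2])
  opt <- optimizer_init(p, config$optimizer)
  n <- length(tr)
  bs <- config$batch_size
  trace <- list()
  skip_counts <- c(bal = 0L, ci = 0L, stab = 0L)
  keep <- 1 - config$dropout

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = bs)
    ep_terms <- NULL
    for (st in starts) {
      idx <- ord[st:min(st + bs - 1, n)]
      if (length(idx) < 4) {
        ## resample a full small batch rather than feed the penalties < 4 rows
        idx <- ord[sample.int(n, min(bs, n))]
      }
      b <- list(X = Xarr[idx, , , drop = FALSE],
                X_clean = Xarr[idx, , , drop = FALSE],
                Z = Zs[idx], M = matrix(Ms[idx]), Y = Ys[idx, , drop = FALSE])
      nb <- length(idx)
      if (config$input_noise_sd > 0)
        b$X <- b$X + array(stats::rnorm(length(b$X), 0, config$input_noise_sd), dim(b$X))
      drop_mask <- if (config$dropout > 0)
        matrix(stats::rbinom(nb * (dim(Xarr)[3] + config$conv_filters[3]), 1, keep) / keep,
               nb) else NULL
      half_a <- sample(rep(c(TRUE, FALSE), length.out = nb))
      fwd <- clae_loss_fwd(p, b, config, drop_mask, half_a)
      skip_counts <- skip_counts + fwd$skipped[names(skip_counts)]
      grads <- clip_grads(clae_loss_bwd(p, fwd, config), config$grad_clip)
      stp <- optimizer_step(p, grads, opt, config)
      p <- stp$params; opt <- stp$state
      ep_terms <- rbind(ep_terms, c(total = fwd$total, fwd$terms, fwd$penalties))
    }
    trace[[ep]] <- colMeans(ep_terms)
    if (!is.finite(trace[[ep]][["total"]]))
      stopf("training diverged at epoch %d", ep)
  }
  trace_df <- if (length(trace)) data.frame(epoch = seq_along(trace),
                                            do.call(rbind, trace)) else NULL
  structure(list(params = p, config = config,
                 target_scaler = list(M = scM, Z = scZ, Y = scY),
                 scaler = mw$scaler, trace = trace_df, skip_counts = skip_counts),
            class = "clae_model")
}

#' @export
print.clae_model <- function(x, ...) {
  cat(sprintf("clae_model: %s encoder, latent dim %d, %d epochs (%s)\n",
              x$config$architecture, x$config$latent_dim, x$config$epochs,
              x$config$optimizer))
  if (!is.null(x$trace))
    cat(sprintf("final loss %.4f (out %.4f, bal %.4f)\n",
                utils::tail(x$trace$total, 1), utils::tail(x$trace$out, 1),
                utils::tail(x$trace$bal, 1)))
  invisible(x)
}

#' Encode windows into pre-treatment embeddings
#'
#' Deterministic inference pass (no noise, no dropout): the embedding is the
#' linear projection of the pooled convolutional features concatenated with
#' the per-channel temporal means. Inputs must carry exactly the five
#' pre-treatment channels; the bolus channel is absent by construction to
#' prevent mediator leakage.
#'
#' @param mw a standardized `meal_windows` object (or a bare n x 24 x 5
#'   array of standardized pre-meal matrices).
#' @param model a trained `clae_model`.
#' @return object of class `embedding_set`: list with `phi` (n x latent_dim
#'   matrix), `split` labels (when available) and `provenance`.
#' @export
clae_encode <- function(mw, model) {
  Xarr <- if (is.array(mw)) mw else mw$pre_std
  if (length(dim(Xarr)) != 3 || dim(Xarr)[3] != 5)
    stopf("encoder expects 5 pre-treatment channels, got %s",
          paste(dim(Xarr), collapse = " x "))
  phi <- encoder_fwd(model$params, Xarr)$phi
  colnames(phi) <- paste0("phi", seq_len(ncol(phi)))
  structure(list(phi = phi,
                 split = if (!is.array(mw)) mw$meta$split else NULL,
                 provenance = list(seed = model$config$seed,
                                   config_hash = config_hash(model$config))),
            class = "embedding_set")
}

config_hash <- function(cfg) {
  r <- utils::head(as.integer(charToRaw(paste(
    utils::capture.output(utils::str(cfg)), collapse = ""))), 10000)
  sum(r * seq_along(r)) %% 1e9
}

#' Covariate balance score of an embedding
#'
#' One minus the mean absolute Pearson correlation between the embedding
#' dimensions and the treatment; lies in \[0, 1\] and equals 1 when the
#' embedding is exactly uncorrelated with treatment in-sample.
#'
#' @param phi n x d embedding matrix.
#' @param Z treatment vector.
#' @return scalar in \[0, 1\].
#' @export
balance_score <- function(phi, Z) {
  cors <- suppressWarnings(apply(phi, 2, stats::cor, y = Z))
  cors[!is.finite(cors)] <- 0
  1 - mean(abs(cors))
}

## R^2 of a linear regression of y on X (used for encoder diagnostics)
lm_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Encoder diagnostics on one split
#'
#' @param model a trained `clae_model`.
#' @param mw the standardized `meal_windows` the model was trained on.
#' @param split `"test"` or `"train"`.
#' @return list with outcome_r2 (pooled over the six horizons), mediator_r2,
#'   balance (the balance score of phi vs Z), and z_r2 (R^2 of treatment
#'   regressed on phi).
#' @export
clae_metrics <- function(model, mw, split = "test") {
  sel <- mw$meta$split == split
  Xarr <- mw$pre_std[sel, , , drop = FALSE]
  phi <- encoder_fwd(model$params, Xarr)$phi
  p <- model$params
  pred_out <- dense_fwd(phi, p$outW, p$outb)
  scY <- model$target_scaler$Y
  pred_out_raw <- sweep(sweep(pred_out, 2, scY$sd, "*"), 2, scY$mean, "+")
  Y <- as.matrix(mw$meta[sel, paste0("dg_", HORIZONS)])
  out_r2 <- 1 - sum((Y - pred_out_raw)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
  scM <- model$target_scaler$M
  pred_m <- as.numeric(dense_fwd(phi, p$medW, p$medb)) * scM$sd + scM$mean
  M <- mw$meta$M[sel]
  med_r2 <- 1 - sum((M - pred_m)^2) / sum((M - mean(M))^2)
  Z <- mw$meta$Z[sel]
  list(outcome_r2 = out_r2, mediator_r2 = med_r2,
       balance = balance_score(phi, Z), z_r2 = lm_r2(Z, phi))
}

#' Factorial ablation of the causal penalties
#'
#' Trains one model per (penalty configuration, seed) and evaluates
#' test-split diagnostics.
#'
#' @param mw a split, standardized `meal_windows` object.
#' @param penalty_grid named list of penalty-weight vectors
#'   (bal/lin/ci/stab).
#' @param seeds integer vector of training seeds.
#' @param base_config a [clae_config()] supplying everything else.
#' @return data frame with one row per (configuration, seed): outcome R2,
#'   mediator R2, balance score, z_r2.
#' @export
clae_ablation <- function(mw, penalty_grid, seeds = 1:3, base_config = clae_config()) {
  if (length(penalty_grid) < 2) stopf("need at least 2 penalty configurations")
  rows <- list()
  for (cn in names(penalty_grid)) {
    for (sd_ in seeds) {
      cfg <- base_config
      cfg$penalty_weights[names(penalty_grid[[cn]])] <- penalty_grid[[cn]]
      cfg$seed <- as.integer(sd_)
      model <- clae_train(mw, cfg)
      met <- clae_metrics(model, mw, "test")
      rows[[length(rows) + 1L]] <- data.frame(
        configuration = cn, seed = sd_, outcome_r2 = met$outcome_r2,
        mediator_r2 = met$mediator_r2, balance = met$balance, z_r2 = met$z_r2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select the encoder configuration from an ablation table
#'
#' Maximizes the seed-averaged balance score subject to the seed-averaged
#' outcome R^2 meeting a threshold (covariate balance prioritized subject to
#' adequate outcome prediction).
#'
#' @param ablation_table output of [clae_ablation()].
#' @param r2_threshold minimum acceptable outcome R^2.
#' @return the name of the selected configuration.
#' @export
select_encoder <- function(ablation_table, r2_threshold = 0) {
  agg <- stats::aggregate(cbind(outcome_r2, balance) ~ configuration,
                          data = ablation_table, FUN = mean)
  ok <- agg[agg$outcome_r2 >= r2_threshold, ]
  if (!nrow(ok)) stopf("no configuration meets the outcome R^2 threshold %.3f", r2_threshold)
  ok$configuration[which.max(ok$balance)]
}
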