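## Low-level neural-network primitives for the causally-constrained
## autoencoder: 1-D convolutions (im2col), max pooling, global average
## pooling, dense layers, and RMSprop/AdamW update rules. All gradients are
## analytic and verified against central differences in the test suite.
## Activations are 3-d arrays [batch, length, channels].

## shift the length dimension of [n, L, C] by `o` positions, zero padding
shift_len <- function(A, o) {
  if (o == 0) return(A)
  L <- dim(A)[2]
  out <- array(0, dim(A))
  if (o > 0) out[, (1 + o):L, ] <- A[, 1:(L - o), ]
  else out[, 1:(L + o), ] <- A[, (1 - o):L, ]
  out
}

## same-padded kernel-3 1-D convolution; W is [3*C_in, C_out]
conv1d_fwd <- function(A, W, b) {
  n <- dim(A)[1]; L <- dim(A)[2]
  X2 <- cbind(matrix(shift_len(A, 1), n * L),   # receives input at t-1
              matrix(A, n * L),
              matrix(shift_len(A, -1), n * L))  # receives input at t+1
  Z <- sweep(X2 %*% W, 2, b, "+")
  list(out = array(Z, c(n, L, ncol(W))), X2 = X2)
}

conv1d_bwd <- function(dOut, X2, W, dims_in) {
  n <- dims_in[1]; L <- dims_in[2]; C <- dims_in[3]
  dZ <- matrix(dOut, n * L)
  dW <- crossprod(X2, dZ)
  db <- colSums(dZ)
  dX2 <- dZ %*% t(W)
  dA <- array(dX2[, C + seq_len(C)], c(n, L, C))
  dA <- dA + shift_len(array(dX2[, seq_len(C)], c(n, L, C)), -1) +
    shift_len(array(dX2[, 2 * C + seq_len(C)], c(n, L, C)), 1)
  list(dA = dA, dW = dW, db = db)
}

relu_fwd <- function(A) {
  mask <- A > 0
  list(out = A * mask, mask = mask)
}

## max pooling, width 2, stride 2 (length must be even)
pool2_fwd <- function(A) {
  L <- dim(A)[2]
  odd <- A[, seq(1, L, by = 2), , drop = FALSE]
  even <- A[, seq(2, L, by = 2), , drop = FALSE]
  first <- odd >= even
  list(out = pmax(odd, even), first = first)
}

pool2_bwd <- function(dOut, first, dims_in) {
  dA <- array(0, dims_in)
  L <- dims_in[2]
  dA[, seq(1, L, by = 2), ] <- dOut * first
  dA[, seq(2, L, by = 2), ] <- dOut * !first
  dA
}

gap_fwd <- function(A) {
  n <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
  matrix(colMeans(aperm(A, c(2, 1, 3))), n, C)
}

## broadcast dOut[i, c]/L over the length dimension
gap_bwd <- function(dOut, dims_in) {
  n <- dims_in[1]; L <- dims_in[2]; C <- dims_in[3]
  aperm(array(t(dOut / L), c(C, n, L)), c(2, 3, 1))
}

dense_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

dense_bwd <- function(dOut, X, W) {
  list(dX = dOut %*% t(W), dW = crossprod(X, dOut), db = colSums(dOut))
}

## flatten parameter list <-> vector (used by the numeric gradient checks)
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    k <- length(template[[nm]])
    x <- v[pos + seq_len(k)]
    if (is.matrix(template[[nm]])) dim(x) <- dim(template[[nm]])
    out[[nm]] <- x
    pos <- pos + k
  }
  out
}

zero_like <- function(p) lapply(p, function(x) {
  z <- x
  z[] <- 0
  z
})

global_norm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), 0)))

clip_grads <- function(g, max_norm) {
  nrm <- global_norm(g)
  if (is.finite(nrm) && nrm > max_norm) g <- lapply(g, function(x) x * (max_norm / nrm))
  g
}

optimizer_init <- function(params, name) {
  state <- list(t = 0L, v = zero_like(params))
  if (name == "adamw") state$m <- zero_like(params)
  state
}

optimizer_step <- function(params, grads, state, config) {
  lr <- config$lr
  wd <- config$weight_decay
  is_weight <- grepl("W", names(params))
  state$t <- state$t + 1L
  if (config$optimizer == "rmsprop") {
    for (nm in names(params)) {
      state$v[[nm]] <- 0.9 * state$v[[nm]] + 0.1 * grads[[nm]]^2
      upd <- grads[[nm]] / (sqrt(state$v[[nm]]) + 1e-8)
      if (is_weight[match(nm, names(params))]) upd <- upd + wd * params[[nm]]
      params[[nm]] <- params[[nm]] - lr * upd
    }
  } else if (config$optimizer == "adamw") {
    b1 <- 0.9; b2 <- 0.999
    for (nm in names(params)) {
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + 1e-8) +
        if (is_weight[match(nm, names(params))]) wd * params[[nm]] else 0)
    }
  } else stopf("unknown optimizer '%s'", config$optimizer)
  list(params = params, state = state)
}
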