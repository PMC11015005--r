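# Minimal reverse-mode network engine for the 1D ResNet trunk and heads.
# No deep-learning framework ships with this R installation, so the forward
# and backward passes are written against BLAS matrix ops with conv1d
# gather/scatter in C++ (src/conv1d.cpp).
#
# Activation layout: a (B*L) x C matrix, time fastest within a sample.
# Weight layout: conv (k*C_in) x C_out, tap fastest within input channel;
# linear F x O plus length-O bias.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' @noRd
conv_fwd <- function(X, W, B, L, k, stride, pad) {
  conv1d_fwd_cpp(X, W, as.integer(B), as.integer(L), as.integer(k),
                 as.integer(stride), as.integer(pad))
}

#' @noRd
conv_bwd <- function(X, W, dY, B, L, k, stride, pad) {
  conv1d_bwd_cpp(X, W, dY, as.integer(B), as.integer(L), as.integer(k),
                 as.integer(stride), as.integer(pad))
}

#' @noRd
conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# Batch norm over rows (batch x time), per channel column.
#' @noRd
bn_fwd <- function(X, gamma, beta, run_mean, run_var, training) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * rep(ivar, each = n)
    run_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    run_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
    list(Y = xhat * rep(gamma, each = n) + rep(beta, each = n),
         cache = list(xhat = xhat, ivar = ivar, gamma = gamma),
         run_mean = run_mean, run_var = run_var)
  } else {
    ivar <- 1 / sqrt(run_var + BN_EPS)
    xhat <- (X - rep(run_mean, each = n)) * rep(ivar, each = n)
    list(Y = xhat * rep(gamma, each = n) + rep(beta, each = n),
         cache = NULL, run_mean = run_mean, run_var = run_var)
  }
}

#' @noRd
bn_bwd <- function(dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = n)
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
         xhat * rep(colMeans(dxhat * xhat), each = n)) *
        rep(cache$ivar, each = n)
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

#' @noRd
gap_fwd <- function(X, B, L) {
  grp <- rep(seq_len(B), each = L)
  Y <- rowsum(X, grp, reorder = FALSE) / L
  dimnames(Y) <- NULL
  Y
}

#' @noRd
gap_bwd <- function(dY, B, L) {
  dY[rep(seq_len(B), each = L), , drop = FALSE] / L
}

#' @noRd
softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# Cross-entropy of integer labels (1..K) against logits; returns loss and
# gradient w.r.t. logits (already divided by batch size).
#' @noRd
softmax_ce <- function(Z, y) {
  B <- nrow(Z)
  P <- softmax_rows(Z)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / B, P = P)
}

#' @noRd
he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---------------------------------------------------------------------------
# Adam optimiser over a flat named list of arrays.

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' @noRd
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---------------------------------------------------------------------------
# Gradient accumulation helper: sums same-named entries.

#' @noRd
grad_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
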