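# Minimal dense neural-network engine: linear -> tanh -> batch-normalization
# blocks with hand-derived backpropagation and an Adam optimizer. The visible
# network needs exact control over per-module wiring and ablation, so the
# engine is written here rather than bound to an external framework.

BN_EPS <- 1e-5

nn_linear_init <- function(d_in, d_out) {
  # uniform(-1/sqrt(d_in), 1/sqrt(d_in)), the standard dense-layer default
  a <- 1 / sqrt(max(d_in, 1))
  list(W = matrix(runif(d_in * d_out, -a, a), d_in, d_out),
       b = numeric(d_out))
}

nn_bn_init <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d),
       rm = numeric(d), rv = rep(1, d))
}

nn_block_init <- function(d_in, d_out) {
  list(lin = nn_linear_init(d_in, d_out), bn = nn_bn_init(d_out))
}

# Batch normalization. Training mode uses biased batch statistics and updates
# the running estimates; inference mode uses the running estimates, so a
# batch of one equals the corresponding row of a larger batch.
bn_forward <- function(bn, X, training, momentum = 0.1) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * v
  } else {
    mu <- bn$rm
    v <- bn$rv
    xc <- sweep(X, 2, mu)
  }
  sdv <- sqrt(v + BN_EPS)
  xh <- sweep(xc, 2, sdv, "/")
  Y <- sweep(sweep(xh, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(Y = Y, bn = bn, cache = list(xh = xh, sdv = sdv, training = training))
}

bn_backward <- function(bn, cache, dY) {
  xh <- cache$xh
  dgamma <- colSums(dY * xh)
  dbeta <- colSums(dY)
  dxh <- sweep(dY, 2, bn$gamma, "*")
  if (cache$training) {
    # d/dX of ((X - mean)/sd) with batch statistics (biased variance)
    dX <- sweep(dxh, 2, colMeans(dxh)) -
      sweep(xh, 2, colMeans(dxh * xh), "*")
    dX <- sweep(dX, 2, cache$sdv, "/")
  } else {
    dX <- sweep(dxh, 2, cache$sdv, "/")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

block_forward <- function(blk, X, training, momentum = 0.1) {
  Z <- X %*% blk$lin$W
  Z <- sweep(Z, 2, blk$lin$b, "+")
  H <- tanh(Z)
  bf <- bn_forward(blk$bn, H, training, momentum)
  list(Y = bf$Y, bn = bf$bn,
       cache = list(X = X, H = H, bn = bf$cache))
}

block_backward <- function(blk, cache, dY) {
  bb <- bn_backward(blk$bn, cache$bn, dY)
  dZ <- bb$dX * (1 - cache$H * cache$H)
  list(dX = tcrossprod(dZ, blk$lin$W),
       grads = list(lin = list(W = crossprod(cache$X, dZ), b = colSums(dZ)),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

# Adam over an arbitrary nested list of numeric arrays. Only leaves present
# in the gradient tree are updated, so batch-norm running statistics (never
# part of a gradient) are left alone.
adam_init <- function() list(t = 0L, m = list(), v = list())

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      if (is.null(m)) m <- vector("list", length(g))
      if (is.null(v)) v <- vector("list", length(g))
      idx <- names(g) %||% seq_along(g)   # unnamed lists walk by position
      for (nm in idx) {
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) m <- g * 0
    if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(t = t, m = res$m, v = res$v))
}

# Elementwise sum of two congruent gradient trees (b may be NULL).
grad_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    idx <- names(a) %||% seq_along(a)
    for (nm in idx) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
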