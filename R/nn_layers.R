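# Minimal neural-network primitives in base R matrix algebra: linear,
# batch-normalization, ReLU, dropout and embedding layers, each with an
# explicit backward pass, plus the Adam optimizer. Rows are patients.
# All are internal; gradient correctness is asserted against central finite
# differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

nn_linear_fwd <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, X = X)
}

nn_linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# Batch normalization over the rows actually present in the batch.
# Training mode uses biased batch statistics and updates the running
# estimates; eval mode normalizes with the running estimates.
nn_bn_fwd <- function(X, par, training) {
  if (training && nrow(X) > 0) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
    par$run_mean <- BN_MOMENTUM * par$run_mean + (1 - BN_MOMENTUM) * mu
    par$run_var <- BN_MOMENTUM * par$run_var + (1 - BN_MOMENTUM) * v
  } else {
    invstd <- 1 / sqrt(par$run_var + BN_EPS)
    xhat <- sweep(sweep(X, 2, par$run_mean), 2, invstd, "*")
  }
  out <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(out = out, par = par,
       cache = list(xhat = xhat, invstd = invstd, training = training))
}

nn_bn_bwd <- function(dY, cache, par) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, par$gamma, "*")
  if (cache$training) {
    nb <- nrow(xhat)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dX <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)

nn_relu_bwd <- function(dY, cache) dY * cache$mask

# Inverted dropout: active only in training mode; draws from the current
# RNG stream so training remains reproducible under a fixed seed.
nn_dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

nn_embedding_fwd <- function(codes, E) {
  E[codes, , drop = FALSE]
}

nn_embedding_bwd <- function(dY, codes, vocab_rows) {
  dE <- matrix(0, vocab_rows, ncol(dY))
  agg <- rowsum(dY, group = codes)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

# ---- parameter initialization ---------------------------------------------

he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

glorot_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

new_bn_par <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

# ---- Adam ------------------------------------------------------------------

NON_TRAINABLE <- c("run_mean", "run_var")

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One Adam step over a nested parameter list. `grads` mirrors the structure;
# NULL subtrees/leaves are treated as zero gradient (parameter untouched).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.character(nm) && nm %in% NON_TRAINABLE) next
        gi <- if (is.null(g)) NULL else g[[nm]]
        res <- rec(p[[nm]], gi, m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- rec(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# elementwise accumulate two (possibly NULL) gradient trees
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    for (nm in keys) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
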