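# Minimal dense-network machinery: linear layers, batch normalisation,
# leaky ReLU, softmax/sigmoid heads, manual backpropagation and Adam.
# Written in base matrix code; the networks here are small (hundreds of
# units) and train in seconds on one CPU, so no compiled backend is needed.
# All randomness goes through R's RNG so a single set.seed() makes training
# bit-reproducible.

PROB_EPS <- 1e-9 # probability clamp inside every BCE/CE

add_row <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)
mul_row <- function(m, v) m * matrix(v, nrow(m), length(v), byrow = TRUE)

nn_linear <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

linear_fwd <- function(p, x) list(out = add_row(x %*% p$W, p$b), x = x)

linear_bwd <- function(p, cache, d_out) {
  list(dx = d_out %*% t(p$W),
       grads = list(W = crossprod(cache$x, d_out), b = colSums(d_out)))
}

nn_batchnorm <- function(n) {
  list(gamma = rep(1, n), beta = numeric(n),
       rm = numeric(n), rv = rep(1, n))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_fwd <- function(p, x, train) {
  if (train) {
    m <- colMeans(x)
    xc <- add_row(x, -m)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- mul_row(xc, inv)
    n <- nrow(x)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    p$rm <- (1 - BN_MOMENTUM) * p$rm + BN_MOMENTUM * m
    p$rv <- (1 - BN_MOMENTUM) * p$rv + BN_MOMENTUM * unbiased
  } else {
    inv <- 1 / sqrt(p$rv + BN_EPS)
    xhat <- mul_row(add_row(x, -p$rm), inv)
  }
  out <- add_row(mul_row(xhat, p$gamma), p$beta)
  list(out = out, xhat = xhat, inv = inv, params = p)
}

batchnorm_bwd <- function(p, cache, d_out) {
  n <- nrow(d_out)
  dxhat <- mul_row(d_out, p$gamma)
  a <- colSums(dxhat)
  b <- colSums(dxhat * cache$xhat)
  dx <- mul_row(n * dxhat - add_row(matrix(0, n, ncol(d_out)), a) -
                  mul_row(cache$xhat, b),
                cache$inv / n)
  list(dx = dx,
       grads = list(gamma = colSums(d_out * cache$xhat),
                    beta = colSums(d_out), rm = NULL, rv = NULL))
}

LRELU_SLOPE <- 0.01

lrelu_fwd <- function(x) list(out = pmax(x, 0) + LRELU_SLOPE * pmin(x, 0), x = x)
lrelu_bwd <- function(cache, d_out) d_out * ifelse(cache$x > 0, 1, LRELU_SLOPE)

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# d(loss)/d(logits) given d(loss)/d(softmax output) and the output itself.
softmax_bwd <- function(y, d_y) y * (d_y - rowSums(d_y * y))

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# ---- trunk: n_layers x (linear -> [batchnorm] -> leaky ReLU) ----

nn_trunk <- function(n_in, n_hidden, n_layers, batchnorm = TRUE) {
  layers <- vector("list", n_layers)
  d <- n_in
  for (i in seq_len(n_layers)) {
    layers[[i]] <- list(lin = nn_linear(d, n_hidden),
                        bn = if (batchnorm) nn_batchnorm(n_hidden))
    d <- n_hidden
  }
  layers
}

trunk_fwd <- function(trunk, x, train) {
  caches <- vector("list", length(trunk))
  for (i in seq_along(trunk)) {
    lc <- linear_fwd(trunk[[i]]$lin, x)
    if (!is.null(trunk[[i]]$bn)) {
      bc <- batchnorm_fwd(trunk[[i]]$bn, lc$out, train)
      trunk[[i]]$bn <- bc$params
      ac <- lrelu_fwd(bc$out)
    } else {
      bc <- NULL
      ac <- lrelu_fwd(lc$out)
    }
    caches[[i]] <- list(lin = lc, bn = bc, act = ac)
    x <- ac$out
  }
  list(out = x, caches = caches, trunk = trunk)
}

trunk_bwd <- function(trunk, caches, d_out) {
  grads <- vector("list", length(trunk))
  for (i in rev(seq_along(trunk))) {
    d <- lrelu_bwd(caches[[i]]$act, d_out)
    if (!is.null(trunk[[i]]$bn)) {
      bb <- batchnorm_bwd(trunk[[i]]$bn, caches[[i]]$bn, d)
      d <- bb$dx
      bn_grads <- bb$grads
    } else {
      bn_grads <- NULL
    }
    lb <- linear_bwd(trunk[[i]]$lin, caches[[i]]$lin, d)
    grads[[i]] <- list(lin = lb$grads, bn = bn_grads)
    d_out <- lb$dx
  }
  list(dx = d_out, grads = grads)
}

# ---- Adam over nested parameter lists ----

adam_init <- function(params) {
  if (is.list(params)) return(lapply(params, adam_init))
  if (is.null(params)) return(NULL)
  list(m = params * 0, v = params * 0)
}

# Leaves named rm/rv (batch-norm running stats) receive NULL gradients and
# are skipped.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (!is.list(grads)) {
    if (is.null(grads)) return(list(params = params, state = state))
    state$m <- beta1 * state$m + (1 - beta1) * grads
    state$v <- beta2 * state$v + (1 - beta2) * grads^2
    mhat <- state$m / (1 - beta1^t)
    vhat <- state$v / (1 - beta2^t)
    params <- params - lr * mhat / (sqrt(vhat) + eps)
    return(list(params = params, state = state))
  }
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    res <- adam_step(params[[nm]], grads[[nm]], state[[nm]], lr, t,
                     beta1, beta2, eps)
    params[[nm]] <- res$params
    state[[nm]] <- res$state
  }
  list(params = params, state = state)
}
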