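# Minimal feedforward-network engine with analytic backpropagation.
#
# The density estimators in this package are small multilayer perceptrons
# whose outputs parameterize either a Gaussian mixture (MDN) or an
# autoregressive affine transform (MADE).  The networks are deliberately
# implemented directly on top of BLAS-backed matrix algebra: forward and
# backward passes are batched over simulations, and optional binary masks
# on the weight matrices implement the autoregressive constraints.

# Initialize an MLP: sizes = c(n_in, hidden..., n_out).
# Weights ~ N(0, 1/sqrt(fan_in)), output layer scaled down so the
# estimator starts close to a broad standard-normal density.
mlp_init <- function(sizes, seed = NULL, out_scale = 0.01, skip = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_layer <- length(sizes) - 1L
  W <- vector("list", n_layer)
  b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    sdl <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sdl),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
    if (l == n_layer) W[[l]] <- W[[l]] * out_scale
  }
  net <- list(W = W, b = b, sizes = sizes)
  if (skip) {
    # linear shortcut from the input to the output layer, so affine
    # structure in a conditional need not pass through the nonlinearity
    net$W_skip <- matrix(0, sizes[1L], sizes[n_layer + 1L])
  }
  net
}

# Forward pass; masks (same shapes as W, or NULL) gate connections.
# Returns the output matrix plus the per-layer activations needed by
# mlp_backward.  Activation is tanh on hidden layers, identity on output.
mlp_forward <- function(net, X, masks = NULL) {
  n_layer <- length(net$W)
  A <- vector("list", n_layer + 1L)
  A[[1L]] <- X
  for (l in seq_len(n_layer)) {
    Wl <- net$W[[l]]
    if (!is.null(masks)) Wl <- Wl * masks[[l]]
    Z <- A[[l]] %*% Wl
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    if (l == n_layer && !is.null(net$W_skip)) Z <- Z + X %*% net$W_skip
    A[[l + 1L]] <- if (l < n_layer) tanh(Z) else Z
  }
  list(out = A[[n_layer + 1L]], A = A)
}

# Backward pass. dOut: gradient of the scalar loss wrt the network output
# (B x n_out).  Returns parameter gradients (masked where applicable) and
# the gradient with respect to the input matrix.
mlp_backward <- function(net, cache, dOut, masks = NULL) {
  n_layer <- length(net$W)
  dW <- vector("list", n_layer)
  db <- vector("list", n_layer)
  dW_skip <- if (!is.null(net$W_skip)) crossprod(cache$A[[1L]], dOut) else NULL
  delta <- dOut
  for (l in rev(seq_len(n_layer))) {
    if (l < n_layer) {
      # derivative of tanh at the activation value a: 1 - a^2
      delta <- delta * (1 - cache$A[[l + 1L]]^2)
    }
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    if (!is.null(masks)) dW[[l]] <- dW[[l]] * masks[[l]]
    db[[l]] <- colSums(delta)
    Wl <- net$W[[l]]
    if (!is.null(masks)) Wl <- Wl * masks[[l]]
    delta <- tcrossprod(delta, Wl)
  }
  if (!is.null(net$W_skip)) delta <- delta + tcrossprod(dOut, net$W_skip)
  out <- list(dW = dW, db = db, dX = delta)
  if (!is.null(dW_skip)) out$dW_skip <- dW_skip
  out
}

# ---- generic tree utilities for optimizer state -------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) tree_map(f, el)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

# ---- Adam optimizer (default settings) ----------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}
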