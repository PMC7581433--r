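# Mixture density network (MDN): a feedforward network mapping a feature
# vector x to the parameters of a K-component Gaussian mixture over the
# model parameters theta.  Covariances are parameterized by lower-triangular
# Cholesky factors with softplus-positive diagonals; mixture weights by a
# softmax over unconstrained logits.

#' Minimum hidden units per layer for a mixture density network
#'
#' For an MDN with `K` mixture components over `n_params` parameters, the
#' output layer must produce `K` mixture weights plus, per component, a mean
#' vector and the entries of a covariance factor.  A hidden layer narrower
#' than the number of quantities to be emitted bottlenecks the mixture, so
#' each hidden layer should have at least
#' \eqn{K(1 + N_\theta + N_\theta(N_\theta+1)/2) - 1} units.
#'
#' @param K Number of mixture components (positive integer).
#' @param n_params Number of parameters \eqn{N_\theta} to infer.
#' @return Integer: the minimum recommended units per hidden layer.
#' @export
#' @examples
#' min_units(2, 8)   # 89
#' min_units(1, 1)   # 2
min_units <- function(K, n_params) {
  if (length(K) != 1L || length(n_params) != 1L ||
      !is.finite(K) || !is.finite(n_params) ||
      K < 1 || n_params < 1 || K != round(K) || n_params != round(n_params)) {
    stop("`K` and `n_params` must be positive integers", call. = FALSE)
  }
  as.integer(K * (1 + n_params + n_params * (n_params + 1) / 2) - 1)
}

#' Configure a mixture density network estimator
#'
#' @param n_params Dimensionality of the parameter vector theta.
#' @param n_features Dimensionality of the conditioning feature vector x.
#' @param n_components Number of Gaussian mixture components K.
#' @param hidden Integer vector of hidden layer sizes.  Layers narrower than
#'   [min_units()] are allowed but trigger a warning, since they can
#'   bottleneck the mixture parameterization.
#' @param max_epochs,learning_rate,batch_size,patience,val_fraction Training
#'   controls: maximum epochs, Adam learning rate, minibatch size, early
#'   stopping patience (epochs without validation improvement), and held-out
#'   validation fraction.
#' @param skip Add a linear shortcut from the features to the output layer
#'   (default `TRUE`), so nearly affine conditionals are representable
#'   without saturating the nonlinearity.
#' @param embedding Optional fixed embedding `function(x_matrix)` applied to
#'   raw feature rows before normalization and the network (a hook for
#'   compressing image-valued features, e.g. a projection of a pixel-level
#'   spike-triggered average); `n_features` is the embedded dimension.
#' @return An object of class `mdn_config`.
#' @export
mdn_config <- function(n_params, n_features, n_components = 1L,
                       hidden = NULL,
                       max_epochs = 500L, learning_rate = 1e-3,
                       batch_size = 100L, patience = 25L,
                       val_fraction = 0.1, skip = TRUE,
                       embedding = NULL) {
  stopifnot(n_params >= 1, n_features >= 1, n_components >= 1)
  mu <- min_units(n_components, n_params)
  if (is.null(hidden)) hidden <- rep(max(mu, 20L), 2L)
  if (any(hidden < mu)) {
    warning(sprintf(
      "hidden layers of size [%s] are below the recommended minimum of %d units for K=%d, n_params=%d",
      paste(hidden, collapse = ","), mu, n_components, n_params), call. = FALSE)
  }
  structure(list(
    n_params = as.integer(n_params),
    n_features = as.integer(n_features),
    n_components = as.integer(n_components),
    hidden = as.integer(hidden),
    max_epochs = as.integer(max_epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    val_fraction = val_fraction,
    skip = isTRUE(skip),
    embedding = embedding
  ), class = c("mdn_config", "estimator_config"))
}

mdn_out_dim <- function(K, D) {
  as.integer(K + K * D + K * D + K * D * (D - 1) / 2)
}

# index bookkeeping into the flat output vector
mdn_slots <- function(K, D) {
  noff <- D * (D - 1) / 2
  pos <- 0L
  logits <- pos + seq_len(K); pos <- pos + K
  mu <- lapply(seq_len(K), function(k) pos + (k - 1L) * D + seq_len(D))
  pos <- pos + K * D
  diag <- lapply(seq_len(K), function(k) pos + (k - 1L) * D + seq_len(D))
  pos <- pos + K * D
  off <- if (noff > 0) lapply(seq_len(K), function(k) pos + (k - 1L) * noff + seq_len(noff)) else
    replicate(K, integer(0), simplify = FALSE)
  # off-diagonal order: column-major over (i > j)
  ij <- if (noff > 0) {
    cbind(i = unlist(lapply(seq_len(D - 1L), function(j) (j + 1L):D)),
          j = unlist(lapply(seq_len(D - 1L), function(j) rep(j, D - j))))
  } else matrix(integer(0), 0, 2)
  idx_mat <- matrix(NA_integer_, D, D)
  if (noff > 0) idx_mat[ij] <- seq_len(noff)
  list(logits = logits, mu = mu, diag = diag, off = off, ij = ij,
       idx_mat = idx_mat, noff = as.integer(noff))
}

mdn_init <- function(config, seed = NULL) {
  sizes <- c(config$n_features, config$hidden,
             mdn_out_dim(config$n_components, config$n_params))
  net <- mlp_init(sizes, seed = seed, skip = isTRUE(config$skip))
  structure(list(config = config, net = net,
                 slots = mdn_slots(config$n_components, config$n_params)),
            class = "mdn_net")
}

# Core of the MDN: given raw network outputs `out` (B x out_dim) and
# standardized parameters `theta` (B x D), compute the per-sample mixture
# log-density, the gradient of the summed weighted NLL with respect to the
# raw outputs, and optionally the gradient of log q with respect to theta.
#
# All per-component triangular solves are vectorized over the batch:
# L varies per sample, but forward/backward substitution unrolls to D^2
# scalar recurrences each acting on length-B vectors.
mdn_mixture <- function(out, theta, slots, K, D,
                        want_dout = FALSE, want_dtheta = FALSE,
                        sample_w = NULL) {
  B <- nrow(out)
  logits <- out[, slots$logits, drop = FALSE]
  lw <- logits - row_logsumexp(logits)          # log mixture weights
  comp_lp <- matrix(0, B, K)
  ys <- zs <- Ldiags <- Ldraws <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- out[, slots$mu[[k]], drop = FALSE]
    draw <- out[, slots$diag[[k]], drop = FALSE]
    Ld <- softplus(draw) + 1e-6
    Loff <- out[, slots$off[[k]], drop = FALSE]
    d <- theta - mu
    # forward substitution y = L^{-1} d
    y <- matrix(0, B, D)
    for (i in seq_len(D)) {
      acc <- d[, i]
      if (i > 1L) for (j in seq_len(i - 1L)) {
        acc <- acc - Loff[, slots$idx_mat[i, j]] * y[, j]
      }
      y[, i] <- acc / Ld[, i]
    }
    comp_lp[, k] <- -0.5 * D * log(2 * pi) - rowSums(log(Ld)) - 0.5 * rowSums(y^2)
    ys[[k]] <- y; Ldiags[[k]] <- Ld; Ldraws[[k]] <- draw
    if (want_dout || want_dtheta) {
      # backward substitution z = L^{-T} y
      z <- matrix(0, B, D)
      for (i in rev(seq_len(D))) {
        acc <- y[, i]
        if (i < D) for (j in (i + 1L):D) {
          acc <- acc - Loff[, slots$idx_mat[j, i]] * z[, j]
        }
        z[, i] <- acc / Ld[, i]
      }
      zs[[k]] <- z
    }
  }
  joint <- lw + comp_lp
  logq <- row_logsumexp(joint)
  res <- list(logq = logq)
  if (want_dout || want_dtheta) {
    r <- exp(joint - logq)                      # responsibilities B x K
    w <- exp(lw)
    if (want_dout) {
      sw <- if (is.null(sample_w)) rep(1, B) else sample_w
      dout <- matrix(0, B, ncol(out))
      dout[, slots$logits] <- (w - r) * sw      # d(-logq)/dlogits
      for (k in seq_len(K)) {
        rk <- r[, k] * sw
        dout[, slots$mu[[k]]] <- -rk * zs[[k]]
        # dlogN/dL_ii = z_i y_i - 1/L_ii ; chain through softplus
        dldiag <- zs[[k]] * ys[[k]] - 1 / Ldiags[[k]]
        dout[, slots$diag[[k]]] <- -rk * dldiag * softplus_grad(Ldraws[[k]])
        if (slots$noff > 0) {
          dloff <- zs[[k]][, slots$ij[, 1], drop = FALSE] *
                   ys[[k]][, slots$ij[, 2], drop = FALSE]
          dout[, slots$off[[k]]] <- -rk * dloff
        }
      }
      res$dout <- dout
    }
    if (want_dtheta) {
      dth <- matrix(0, B, D)
      for (k in seq_len(K)) dth <- dth - r[, k] * zs[[k]]
      res$dtheta <- dth
    }
  }
  res
}

# Extract mixture parameters (weights, means, Cholesky factors) at a single
# standardized feature vector.
mdn_mixture_params <- function(mnet, xz) {
  cfg <- mnet$config
  out <- mlp_forward(mnet$net, matrix(xz, nrow = 1L))$out
  s <- mnet$slots
  K <- cfg$n_components; D <- cfg$n_params
  lw <- out[, s$logits] - logsumexp(out[, s$logits])
  comps <- lapply(seq_len(K), function(k) {
    L <- diag(softplus(out[, s$diag[[k]]]) + 1e-6, D)
    if (s$noff > 0) L[s$ij] <- out[, s$off[[k]]]
    list(mu = out[, s$mu[[k]]], L = L)
  })
  list(logw = as.numeric(lw), comps = comps)
}

mdn_sample_z <- function(mnet, xz, n) {
  mp <- mdn_mixture_params(mnet, xz)
  K <- length(mp$comps); D <- mnet$config$n_params
  ks <- sample.int(K, n, replace = TRUE, prob = exp(mp$logw))
  eps <- matrix(rnorm(n * D), n, D)
  th <- matrix(0, n, D)
  for (k in seq_len(K)) {
    sel <- ks == k
    if (!any(sel)) next
    th[sel, ] <- sweep(eps[sel, , drop = FALSE] %*% t(mp$comps[[k]]$L),
                       2L, mp$comps[[k]]$mu, "+")
  }
  th
}
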