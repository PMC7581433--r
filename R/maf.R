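# Masked autoregressive flow (MAF): a stack of autoregressive affine
# bijections, each implemented by a masked feedforward network (MADE),
# transforming the parameter vector into a standard-normal base space.
# Conditioning features enter every MADE unmasked.  Dimension order is
# reversed between consecutive bijections so that no dimension is always
# last in the autoregression.

#' Configure a masked autoregressive flow estimator
#'
#' @inheritParams mdn_config
#' @param n_mades Number of stacked autoregressive bijections.
#' @param hidden Hidden layer sizes of each MADE.
#' @return An object of class `maf_config`.
#' @export
maf_config <- function(n_params, n_features, n_mades = 5L,
                       hidden = c(50L, 50L),
                       max_epochs = 500L, learning_rate = 1e-3,
                       batch_size = 100L, patience = 25L,
                       val_fraction = 0.1, embedding = NULL) {
  stopifnot(n_params >= 1, n_features >= 1, n_mades >= 1)
  structure(list(
    n_params = as.integer(n_params),
    n_features = as.integer(n_features),
    n_mades = as.integer(n_mades),
    hidden = as.integer(hidden),
    max_epochs = as.integer(max_epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    val_fraction = val_fraction,
    embedding = embedding
  ), class = c("maf_config", "estimator_config"))
}

# MADE degree assignment and masks.  Input theta dims get degrees 1..D;
# conditioning features are unmasked (connected everywhere); hidden units
# cycle through degrees 1..max(D-1, 1); the two output blocks (mu, alpha)
# use strict masks so that output i depends only on theta_{<i} and x.
made_masks <- function(D, n_features, hidden) {
  deg_in <- seq_len(D)
  deg_hidden <- lapply(hidden, function(H) {
    rep_len(seq_len(max(D - 1L, 1L)), H)
  })
  masks <- vector("list", length(hidden) + 1L)
  # input layer: rows = D theta inputs then n_features unmasked inputs
  m1 <- outer(deg_in, deg_hidden[[1L]], "<=")
  masks[[1L]] <- rbind(m1 * 1, matrix(1, n_features, length(deg_hidden[[1L]])))
  if (length(hidden) > 1L) {
    for (l in 2:length(hidden)) {
      masks[[l]] <- outer(deg_hidden[[l - 1L]], deg_hidden[[l]], "<=") * 1
    }
  }
  deg_out <- rep(seq_len(D), 2L)  # mu_1..mu_D, alpha_1..alpha_D
  masks[[length(hidden) + 1L]] <-
    outer(deg_hidden[[length(hidden)]], deg_out, "<") * 1
  masks
}

maf_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  D <- config$n_params
  mades <- vector("list", config$n_mades)
  masks <- made_masks(D, config$n_features, config$hidden)
  for (t in seq_len(config$n_mades)) {
    sizes <- c(D + config$n_features, config$hidden, 2L * D)
    net <- mlp_init(sizes)   # consumes the seeded RNG stream sequentially
    perm <- if (t %% 2L == 0L) rev(seq_len(D)) else seq_len(D)
    mades[[t]] <- list(net = net, perm = perm)
  }
  structure(list(config = config, mades = mades, masks = masks),
            class = "maf_net")
}

# Forward (density) direction: map standardized theta to the base space.
# Returns base-space values, per-made caches for backprop, and log|det J|.
maf_forward <- function(mnet, theta, x, keep_cache = FALSE) {
  D <- mnet$config$n_params
  B <- nrow(theta)
  z <- theta
  logdet <- numeric(B)
  caches <- if (keep_cache) vector("list", length(mnet$mades)) else NULL
  for (t in seq_along(mnet$mades)) {
    md <- mnet$mades[[t]]
    zp <- z[, md$perm, drop = FALSE]
    fw <- mlp_forward(md$net, cbind(zp, x), masks = mnet$masks)
    mu <- fw$out[, seq_len(D), drop = FALSE]
    alpha <- fw$out[, D + seq_len(D), drop = FALSE]
    u <- (zp - mu) * exp(-alpha)
    logdet <- logdet - rowSums(alpha)
    if (keep_cache) caches[[t]] <- list(fw = fw, zp = zp, mu = mu,
                                        alpha = alpha, u = u)
    z <- u
  }
  list(z = z, logdet = logdet, caches = caches)
}

maf_log_prob_z <- function(mnet, theta, x) {
  f <- maf_forward(mnet, theta, x)
  D <- mnet$config$n_params
  -0.5 * D * log(2 * pi) - 0.5 * rowSums(f$z^2) + f$logdet
}

# Loss (weighted NLL) and gradients with respect to all MADE parameters.
maf_loss_grad <- function(mnet, theta, x, sample_w) {
  D <- mnet$config$n_params
  f <- maf_forward(mnet, theta, x, keep_cache = TRUE)
  nll <- 0.5 * D * log(2 * pi) + 0.5 * rowSums(f$z^2) - f$logdet
  loss <- sum(sample_w * nll)
  g <- f$z * sample_w                 # d loss / d z_final
  grads <- vector("list", length(mnet$mades))
  for (t in rev(seq_along(mnet$mades))) {
    cc <- f$caches[[t]]
    emal <- exp(-cc$alpha)
    dalpha <- sample_w * 1 - g * cc$u     # direct logdet term + chain via u
    dmu <- -g * emal
    dzp_direct <- g * emal
    dout <- cbind(dmu, dalpha)
    bw <- mlp_backward(mnet$mades[[t]]$net, cc$fw, dout, masks = mnet$masks)
    dzp <- dzp_direct + bw$dX[, seq_len(D), drop = FALSE]
    g <- dzp[, order(mnet$mades[[t]]$perm), drop = FALSE]  # un-permute
    grads[[t]] <- list(net = list(W = bw$dW, b = bw$db))
  }
  list(loss = loss, grads = grads)
}

# Inverse direction (sampling): map base-space u back to theta.  The
# autoregressive structure requires one network pass per dimension.
maf_inverse <- function(mnet, u, x) {
  D <- mnet$config$n_params
  for (t in rev(seq_along(mnet$mades))) {
    md <- mnet$mades[[t]]
    zp <- matrix(0, nrow(u), D)
    for (i in seq_len(D)) {
      fw <- mlp_forward(md$net, cbind(zp, x), masks = mnet$masks)
      mu <- fw$out[, i]
      alpha <- fw$out[, D + i]
      zp[, i] <- u[, i] * exp(alpha) + mu
    }
    u <- zp[, order(md$perm), drop = FALSE]
  }
  u
}
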