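# Training of conditional density estimators by (weighted) negative
# log-density minimization with Adam, early stopping on a held-out split,
# and z-scoring of both parameters and features using training statistics.

zstats <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

zscore <- function(M, zs) sweep(sweep(M, 2L, zs$mean, "-"), 2L, zs$sd, "/")
unzscore <- function(M, zs) sweep(sweep(M, 2L, zs$sd, "*"), 2L, zs$mean, "+")

# Split a simulation table (or theta/x matrices) into training inputs.
resolve_training_data <- function(data, theta = NULL, x = NULL) {
  if (is.data.frame(data)) {
    tm <- table_matrices(data)
    keep <- tm$valid
    if (!any(keep)) stop("no valid rows in the simulation table", call. = FALSE)
    list(theta = tm$theta[keep, , drop = FALSE],
         x = tm$x[keep, , drop = FALSE], keep = keep)
  } else if (is.matrix(data)) {
    stopifnot(is.matrix(x))
    list(theta = data, x = x, keep = rep(TRUE, nrow(data)))
  } else {
    stop("`data` must be a simulation table or a parameter matrix", call. = FALSE)
  }
}

#' Train a conditional density estimator on simulator output
#'
#' Fits a mixture density network or masked autoregressive flow to rows of
#' (parameters, features) by minimizing the weighted negative log-density
#' \eqn{\sum_j w_j\, (-\log q(\theta_j | x_j))} with the Adam optimizer at
#' default settings.  Both parameters and features are z-scored with
#' training-set statistics (stored in the returned estimator); a held-out
#' validation split provides early stopping.
#'
#' @param data A simulation table (as returned by [run_simulations()]), or a
#'   numeric matrix of parameters (then `x` must be the feature matrix).
#'   Invalid rows of a table are excluded.
#' @param config An [mdn_config()] or [maf_config()] object.
#' @param weights Optional nonnegative per-row weights (after removal of
#'   invalid rows they must match the number of training rows, or the table
#'   rows, in length).  Defaults to 1.
#' @param x Feature matrix when `data` is a matrix.
#' @param seed Integer seed controlling weight initialization, data split
#'   and minibatch shuffling.
#' @param init Optional estimator to warm-start from (same architecture).
#' @param verbose Print per-epoch losses.
#' @return An object of class `density_estimator` with elements `config`,
#'   the fitted network, normalization statistics, and a loss trace.
#' @export
train_estimator <- function(data, config, weights = NULL, x = NULL,
                            seed = 1L, init = NULL, verbose = FALSE) {
  td <- resolve_training_data(data, x = x)
  theta <- td$theta; xm <- td$x
  n <- nrow(theta)
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) == length(td$keep) && length(td$keep) != n) {
    weights <- weights[td$keep]
  }
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights >= 0))
  if (is.function(config$embedding)) xm <- config$embedding(xm)
  stopifnot(ncol(xm) == config$n_features)
  check_finite(theta, "theta"); check_finite(xm, "features")

  zs_theta <- zstats(theta); zs_x <- zstats(xm)
  tz <- zscore(theta, zs_theta); xz <- zscore(xm, zs_x)
  w <- weights / mean(weights)          # normalize to mean 1

  set.seed(child_seed(seed, 0L))
  n_val <- if (n >= 20L) max(1L, floor(config$val_fraction * n)) else 0L
  idx <- sample.int(n)
  val_idx <- head(idx, n_val)
  tr_idx <- setdiff(idx, val_idx)

  mnet <- if (!is.null(init)) {
    init$net_obj
  } else if (inherits(config, "mdn_config")) {
    mdn_init(config, seed = child_seed(seed, 1L))
  } else {
    maf_init(config, seed = child_seed(seed, 1L))
  }

  batch_loss_grad <- function(mnet, bi) {
    if (inherits(config, "mdn_config")) {
      fw <- mlp_forward(mnet$net, xz[bi, , drop = FALSE])
      mm <- mdn_mixture(fw$out, tz[bi, , drop = FALSE], mnet$slots,
                        config$n_components, config$n_params,
                        want_dout = TRUE, sample_w = w[bi])
      bw <- mlp_backward(mnet$net, fw, mm$dout)
      g <- list(W = bw$dW, b = bw$db)
      if (!is.null(bw$dW_skip)) g$W_skip <- bw$dW_skip
      list(loss = -sum(w[bi] * mm$logq), grads = list(net = g))
    } else {
      lg <- maf_loss_grad(mnet, tz[bi, , drop = FALSE],
                          xz[bi, , drop = FALSE], w[bi])
      list(loss = lg$loss, grads = list(mades = lg$grads))
    }
  }
  eval_loss <- function(mnet, bi) {
    if (length(bi) == 0L) return(NA_real_)
    lp <- if (inherits(config, "mdn_config")) {
      fw <- mlp_forward(mnet$net, xz[bi, , drop = FALSE])
      mdn_mixture(fw$out, tz[bi, , drop = FALSE], mnet$slots,
                  config$n_components, config$n_params)$logq
    } else {
      maf_log_prob_z(mnet, tz[bi, , drop = FALSE], xz[bi, , drop = FALSE])
    }
    -sum(w[bi] * lp) / length(bi)
  }

  params <- if (inherits(config, "mdn_config")) {
    p0 <- list(W = mnet$net$W, b = mnet$net$b)
    if (!is.null(mnet$net$W_skip)) p0$W_skip <- mnet$net$W_skip
    list(net = p0)
  } else {
    list(mades = lapply(mnet$mades, function(m) list(net = list(W = m$net$W, b = m$net$b))))
  }
  put_params <- function(mnet, params) {
    if (inherits(config, "mdn_config")) {
      mnet$net$W <- params$net$W; mnet$net$b <- params$net$b
      if (!is.null(params$net$W_skip)) mnet$net$W_skip <- params$net$W_skip
    } else {
      for (t in seq_along(mnet$mades)) {
        mnet$mades[[t]]$net$W <- params$mades[[t]]$net$W
        mnet$mades[[t]]$net$b <- params$mades[[t]]$net$b
      }
    }
    mnet
  }

  opt <- adam_init(params)
  bs <- min(config$batch_size, length(tr_idx))
  best_val <- Inf; best_params <- params
  trace_train <- numeric(0); trace_val <- numeric(0)
  epochs_left <- config$max_epochs

  # two-stage schedule: when validation stalls, restore the best weights
  # and continue once at a tenfold smaller learning rate before stopping
  # for good (sharp, nearly deterministic conditionals benefit from the
  # fine-tuning stage)
  for (stage in 0:1) {
    lr <- config$learning_rate / 10^stage
    wait <- 0L
    while (epochs_left > 0L) {
      epochs_left <- epochs_left - 1L
      sh <- sample(tr_idx)
      nb <- ceiling(length(sh) / bs)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        bi <- sh[((b - 1L) * bs + 1L):min(b * bs, length(sh))]
        lg <- batch_loss_grad(mnet, bi)
        st <- adam_step(params, lg$grads, opt, lr = lr)
        params <- st$params; opt <- st$state
        mnet <- put_params(mnet, params)
        ep_loss <- ep_loss + lg$loss
      }
      trace_train <- c(trace_train, ep_loss / length(tr_idx))
      if (n_val > 0L) {
        vl <- eval_loss(mnet, val_idx)
        trace_val <- c(trace_val, vl)
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_params <- params; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      }
      if (verbose) message(sprintf("epoch %d train %.4f val %.4f",
                                   length(trace_train),
                                   tail(trace_train, 1),
                                   if (n_val > 0) tail(trace_val, 1) else NA))
    }
    if (n_val == 0L || epochs_left == 0L) break
    params <- best_params
    mnet <- put_params(mnet, params)
  }
  if (n_val > 0L) mnet <- put_params(mnet, best_params)

  structure(list(
    config = config,
    net_obj = mnet,
    zs_theta = zs_theta,
    zs_x = zs_x,
    trace = list(train = trace_train, val = trace_val),
    seed = seed,
    n_train = n
  ), class = c(if (inherits(config, "mdn_config")) "mdn_estimator" else "maf_estimator",
               "density_estimator"))
}

#' Conditional log-density of a trained estimator
#'
#' @param est A `density_estimator` from [train_estimator()].
#' @param theta Parameter vector or matrix (rows = evaluation points).
#' @param x Feature vector (single conditioning point) or matrix matching
#'   `theta` row-wise.
#' @return Numeric vector of log-densities (natural parameter units; the
#'   z-scoring Jacobian is included).
#' @export
estimator_log_prob <- function(est, theta, x) {
  theta <- as_row_matrix(theta)
  x <- as_row_matrix(x)
  if (is.function(est$config$embedding)) x <- est$config$embedding(x)
  if (ncol(theta) != est$config$n_params) stop("theta dimension mismatch", call. = FALSE)
  if (ncol(x) != est$config$n_features) stop("feature dimension mismatch", call. = FALSE)
  if (nrow(x) == 1L && nrow(theta) > 1L) x <- x[rep(1L, nrow(theta)), , drop = FALSE]
  tz <- zscore(theta, est$zs_theta); xz <- zscore(x, est$zs_x)
  lp <- if (inherits(est, "mdn_estimator")) {
    fw <- mlp_forward(est$net_obj$net, xz)
    mdn_mixture(fw$out, tz, est$net_obj$slots,
                est$config$n_components, est$config$n_params)$logq
  } else {
    maf_log_prob_z(est$net_obj, tz, xz)
  }
  lp - sum(log(est$zs_theta$sd))
}

#' Gradient of the estimator log-density with respect to theta
#'
#' Analytic for mixture density networks; masked autoregressive flows fall
#' back to central finite differences.
#'
#' @inheritParams estimator_log_prob
#' @param eps Finite-difference step (MAF only).
#' @return Matrix of gradients, one row per row of `theta`.
#' @export
estimator_log_prob_grad <- function(est, theta, x, eps = 1e-5) {
  theta <- as_row_matrix(theta)
  if (inherits(est, "mdn_estimator")) {
    x <- as_row_matrix(x)
    if (nrow(x) == 1L && nrow(theta) > 1L) x <- x[rep(1L, nrow(theta)), , drop = FALSE]
    tz <- zscore(theta, est$zs_theta); xz <- zscore(x, est$zs_x)
    fw <- mlp_forward(est$net_obj$net, xz)
    mm <- mdn_mixture(fw$out, tz, est$net_obj$slots,
                      est$config$n_components, est$config$n_params,
                      want_dtheta = TRUE)
    sweep(mm$dtheta, 2L, est$zs_theta$sd, "/")
  } else {
    numeric_grad(function(th) estimator_log_prob(est, th, x), theta, eps = eps)
  }
}

# central finite-difference gradient, row-wise over a matrix of points
numeric_grad <- function(f, theta, eps = 1e-5) {
  theta <- as_row_matrix(theta)
  G <- matrix(0, nrow(theta), ncol(theta))
  for (j in seq_len(ncol(theta))) {
    tp <- theta; tm <- theta
    h <- eps * pmax(1, abs(theta[, j]))
    tp[, j] <- tp[, j] + h; tm[, j] <- tm[, j] - h
    G[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  G
}

#' Draw samples from the conditional density at a feature vector
#'
#' @inheritParams estimator_log_prob
#' @param x A single feature vector to condition on.
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` x `n_params` matrix of parameter samples.
#' @export
estimator_sample <- function(est, x, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as_row_matrix(x)
  if (is.function(est$config$embedding)) x <- est$config$embedding(x)
  xz <- as.numeric(zscore(x, est$zs_x))
  th <- if (inherits(est, "mdn_estimator")) {
    mdn_sample_z(est$net_obj, xz, n)
  } else {
    D <- est$config$n_params
    u <- matrix(rnorm(n * D), n, D)
    maf_inverse(est$net_obj, u, matrix(xz, n, length(xz), byrow = TRUE))
  }
  if (!all(is.finite(th))) stop("estimator produced non-finite samples (degenerate weights?)", call. = FALSE)
  unzscore(th, est$zs_theta)
}

#' Serialize an estimator to a checkpoint with a plain-text metadata header
#'
#' The trainable state is written as a single binary checkpoint (RDS); a
#' sidecar `<path>.meta.yaml` records architecture, normalization
#' statistics and seed in human-readable form.
#'
#' @param est A `density_estimator`.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_estimator <- function(est, path) {
  saveRDS(est, path)
  meta <- list(
    class = class(est)[1L],
    config = unclass(est$config),
    n_train = est$n_train,
    seed = est$seed,
    zscore = list(theta_mean = as.numeric(est$zs_theta$mean),
                  theta_sd = as.numeric(est$zs_theta$sd),
                  x_mean = as.numeric(est$zs_x$mean),
                  x_sd = as.numeric(est$zs_x$sd))
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) readRDS(path)
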