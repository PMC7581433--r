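# Broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   facet_wrap labs theme_minimal geom_density geom_vline scale_fill_viridis_c
NULL

#' Tidy a posterior: per-parameter summaries from posterior samples
#'
#' @param x An `snpe_posterior`.
#' @param n Number of posterior samples used for the summaries.
#' @param seed Integer seed.
#' @param conf_level Credible-interval mass.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`
#'   (posterior mean), `std.error` (posterior SD), `conf.low`,
#'   `conf.high`.
#' @method tidy snpe_posterior
#' @export
tidy.snpe_posterior <- function(x, n = 1000L, seed = 1L, conf_level = 0.95,
                                ...) {
  th <- posterior_sample(x, n, seed = seed)
  a <- (1 - conf_level) / 2
  nm <- x$prior$names %||% paste0("theta_", seq_len(ncol(th)))
  tibble::tibble(
    term = nm,
    estimate = colMeans(th),
    std.error = apply(th, 2L, sd),
    conf.low = apply(th, 2L, quantile, probs = a),
    conf.high = apply(th, 2L, quantile, probs = 1 - a)
  )
}

#' One-row summary of a posterior fit
#'
#' @inheritParams tidy.snpe_posterior
#' @return A tibble with rounds, training-set size, estimator family and
#'   final training loss.
#' @method glance snpe_posterior
#' @export
glance.snpe_posterior <- function(x, ...) {
  est <- x$estimator
  tibble::tibble(
    rounds = x$rounds,
    n_train = est$n_train,
    estimator = if (inherits(est, "mdn_estimator")) "mdn" else "maf",
    epochs = length(est$trace$train),
    final_loss = tail(est$trace$train, 1L)
  )
}

#' @method tidy density_estimator
#' @export
tidy.density_estimator <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$trace$train),
    train_loss = x$trace$train,
    val_loss = if (length(x$trace$val)) x$trace$val else NA_real_
  )
}

#' @method glance density_estimator
#' @export
glance.density_estimator <- function(x, ...) {
  tibble::tibble(
    family = class(x)[1L],
    n_train = x$n_train,
    epochs = length(x$trace$train),
    final_train_loss = tail(x$trace$train, 1L),
    best_val_loss = if (length(x$trace$val)) min(x$trace$val) else NA_real_
  )
}

#' Marginal posterior densities
#'
#' @param object An `snpe_posterior`.
#' @param n Posterior samples to draw.
#' @param seed Integer seed.
#' @param true_theta Optional ground-truth parameter vector drawn as
#'   vertical lines.
#' @param ... Unused.
#' @return A ggplot object with one facet per parameter.
#' @method autoplot snpe_posterior
#' @export
autoplot.snpe_posterior <- function(object, n = 1000L, seed = 1L,
                                    true_theta = NULL, ...) {
  th <- posterior_sample(object, n, seed = seed)
  nm <- object$prior$names %||% paste0("theta_", seq_len(ncol(th)))
  df <- tibble::tibble(
    term = factor(rep(nm, each = nrow(th)), levels = nm),
    value = as.numeric(th)
  )
  p <- ggplot(df, aes(x = .data$value)) +
    geom_density(fill = "steelblue", alpha = 0.4) +
    facet_wrap(~term, scales = "free") +
    labs(x = "parameter value", y = "posterior density") +
    theme_minimal()
  if (!is.null(true_theta)) {
    vl <- tibble::tibble(term = factor(nm, levels = nm), value = true_theta)
    p <- p + geom_vline(data = vl, aes(xintercept = .data$value),
                        linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Heatmap of a two-dimensional conditional posterior
#'
#' @param object A 2-D `conditional_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conditional_grid
#' @export
autoplot.conditional_grid <- function(object, ...) {
  stopifnot(length(object$dims) == 2L)
  df <- expand.grid(a = object$axes[[1L]], b = object$axes[[2L]])
  df$density <- as.numeric(object$density)
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = sprintf("theta[%d]", object$dims[1L]),
         y = sprintf("theta[%d]", object$dims[2L]),
         fill = "density") +
    theme_minimal()
}

#' Training-loss trace of a density estimator
#'
#' @param object A `density_estimator`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_estimator
#' @export
autoplot.density_estimator <- function(object, ...) {
  df <- tidy.density_estimator(object)
  ggplot(df, aes(x = .data$epoch, y = .data$train_loss)) +
    geom_line() +
    labs(x = "epoch", y = "weighted NLL per sample") +
    theme_minimal()
}

#' Voltage trace plots
#'
#' @param object An `hh_trace` or `stg_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hh_trace
#' @export
autoplot.hh_trace <- function(object, ...) {
  df <- tibble::tibble(t = object$t, v = object$v)
  ggplot(df, aes(x = .data$t, y = .data$v)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "membrane potential (mV)") +
    theme_minimal()
}

#' @rdname autoplot.hh_trace
#' @method autoplot stg_trace
#' @export
autoplot.stg_trace <- function(object, ...) {
  df <- tibble::tibble(
    t = rep(object$t, times = 3L),
    v = as.numeric(t(object$v)),
    neuron = factor(rep(c("AB/PD", "LP", "PY"), each = length(object$t)),
                    levels = c("AB/PD", "LP", "PY"))
  )
  ggplot(df, aes(x = .data$t, y = .data$v)) +
    geom_line(linewidth = 0.25) +
    facet_wrap(~neuron, ncol = 1L) +
    labs(x = "time (ms)", y = "membrane potential (mV)") +
    theme_minimal()
}

#' Posterior log-density profile along an optimized path
#'
#' @param path A `posterior_path`.
#' @param post Posterior-like object.
#' @return A ggplot of `log p(gamma(s) | x_o)` against `s`.
#' @export
plot_path_profile <- function(path, post) {
  pd <- path_discretize(path)
  df <- tibble::tibble(s = pd$s, log_prob = geo_log_prob(post, pd$G))
  ggplot(df, aes(x = .data$s, y = .data$log_prob)) +
    geom_line() +
    labs(x = "path position s", y = "posterior log-density") +
    theme_minimal()
}
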