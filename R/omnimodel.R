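# Non-inactivating potassium channel family ("Omnimodel"): an 8-parameter
# kinetics model whose steady-state activation has slope/offset parameters
# and whose time-constant curve has center, amplitude and four shape
# parameters.  The channel is probed by five noisy voltage-clamp protocols
# and current responses are compressed to 55 summary features (10 PCA
# coefficients + 1 offset per protocol).

#' Steady-state activation of the channel family
#'
#' \eqn{m_\infty(V) = 1 / (1 + e^{-\theta_1 V + \theta_2})}; strictly
#' increasing in V for positive slope.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param theta1 Slope parameter.
#' @param theta2 Offset parameter.
#' @return Activation values in (0, 1).
#' @export
omni_steady_state <- function(V, theta1, theta2) {
  1 / (1 + exp(-theta1 * V + theta2))
}

#' Voltage-dependent activation time constant
#'
#' \eqn{\tau_m(V) = \theta_4 / (e^{-[\theta_5 \Delta + \theta_6 \Delta^2]}
#' + e^{\theta_7 \Delta + \theta_8 \Delta^2})} with
#' \eqn{\Delta = V - \theta_3}; always positive.  Exponents are clamped at
#' +/-60 to avoid overflow at extreme voltages (clamped evaluations are
#' flagged via `attr(, "clamped")`).
#'
#' @param V Membrane potential (mV), vectorized.
#' @param theta Numeric vector with elements 3..8 of the parameter vector
#'   (i.e. `theta[1]` is the center theta3).
#' @return Time constants in ms.
#' @export
omni_time_constant <- function(V, theta) {
  d <- V - theta[1L]
  e1 <- -(theta[3L] * d + theta[4L] * d^2)
  e2 <- theta[5L] * d + theta[6L] * d^2
  clamped <- abs(e1) > 60 | abs(e2) > 60
  tau <- theta[2L] / (exp(pmin(pmax(e1, -60), 60)) + exp(pmin(pmax(e2, -60), 60)))
  attr(tau, "clamped") <- any(clamped)
  tau
}

#' Prior over the 8 channel parameters
#'
#' Wide box-uniform prior: slope in (0,1), offset in (-10,10), time-constant
#' center in (-120,120), amplitude in (0,2000) ms, and the four shape
#' parameters in (0,0.5) / (0,0.05) pairs.
#'
#' @return A `prior_box` over 8 dimensions.
#' @export
omnimodel_prior <- function() {
  prior_box(
    lower = c(0, -10, -120, 0, 0, 0, 0, 0),
    upper = c(1, 10, 120, 2000, 0.5, 0.05, 0.5, 0.05),
    names = paste0("theta", 1:8)
  )
}

#' Voltage-clamp protocol set
#'
#' Five protocols probing activation, inactivation-style holding ladders,
#' deactivation tails, a voltage ramp, and an action-potential-shaped
#' command.  Each is a command waveform V(t) at resolution `dt`; Gaussian
#' noise of SD 0.5 mV is added per sample at simulation time.
#'
#' @param dt Time step in ms (must be <= 0.1).
#' @return Named list of protocols, each with `name`, `v` (mV waveform)
#'   and `dt`.
#' @export
clamp_protocols <- function(dt = 0.025) {
  stopifnot(dt <= 0.1)
  seg <- function(v, ms) rep(v, round(ms / dt))
  t_ap <- seq(0, 150 - dt, by = dt)
  ap_wave <- -70 + 110 * (
    exp(-(t_ap - 30)^2 / (2 * 1.5^2)) +
    exp(-(t_ap - 60)^2 / (2 * 1.5^2)) +
    exp(-(t_ap - 90)^2 / (2 * 1.5^2)) +
    exp(-(t_ap - 120)^2 / (2 * 1.5^2)))
  list(
    activation = list(name = "activation", dt = dt,
      v = c(seg(-80, 10), seg(-40, 30), seg(-20, 30), seg(0, 30),
            seg(20, 30), seg(40, 30))),
    inactivation = list(name = "inactivation", dt = dt,
      v = c(seg(-100, 25), seg(-80, 25), seg(-60, 25), seg(-40, 25),
            seg(-20, 25), seg(40, 35))),
    deactivation = list(name = "deactivation", dt = dt,
      v = c(seg(-80, 10), seg(40, 40), seg(-20, 35), seg(-60, 35),
            seg(-100, 35))),
    ramp = list(name = "ramp", dt = dt,
      v = c(seg(-80, 10), seq(-80, 40, length.out = round(150 / dt)))),
    action_potential = list(name = "action_potential", dt = dt, v = ap_wave)
  )
}

#' Simulate the normalized current response to one clamp protocol
#'
#' Integrates the gating variable under the noisy command voltage with an
#' exponential-Euler scheme and returns the max-normalized potassium
#' current \eqn{I_K = \bar g_K m (V - E_K)} at stored time points.
#'
#' @param theta Channel parameter vector (length 8).
#' @param protocol One protocol from [clamp_protocols()].
#' @param seed Optional integer seed (controls the voltage noise).
#' @param noise_sd Command-voltage noise SD in mV (default 0.5).
#' @param e_k Potassium reversal potential (mV).
#' @param store_every Keep every n-th sample.
#' @return Numeric trace of normalized current with attribute `time` (ms).
#' @export
simulate_current <- function(theta, protocol, seed = NULL, noise_sd = 0.5,
                             e_k = -107, store_every = 20L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(protocol$dt <= 0.1, length(theta) == 8L)
  tr <- omnimodel_trace_cpp(as.numeric(theta), protocol$v, protocol$dt,
                            e_k, noise_sd, as.integer(store_every))
  if (!all(is.finite(tr))) stop("non-finite channel state", call. = FALSE)
  m <- max(abs(tr))
  if (m > 0) tr <- tr / m
  attr(tr, "time") <- (seq_along(tr) - 1L) * protocol$dt * store_every
  tr
}

#' Simulate all protocols for one parameter vector
#'
#' @inheritParams simulate_current
#' @param protocols Protocol list from [clamp_protocols()].
#' @return Named list of normalized current traces.
#' @export
simulate_channel <- function(theta, protocols = clamp_protocols(),
                             seed = NULL, noise_sd = 0.5, e_k = -107,
                             store_every = 20L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(protocols, function(p)
    simulate_current(theta, p, seed = NULL, noise_sd = noise_sd,
                     e_k = e_k, store_every = store_every))
}

#' Fit the PCA summary-feature basis from training simulations
#'
#' Per protocol, the basis holds the 10 leading principal-component
#' loading vectors (orthonormal) of the training traces; features of a new
#' trace are its least-squares coefficients on these loadings plus a
#' constant offset regressor (11 per protocol, 55 in total).
#'
#' @param train_traces Named list (one entry per protocol) of matrices,
#'   rows = training simulations, columns = time points (>= 50 rows each).
#' @param n_components Principal components per protocol (default 10).
#' @param provenance Optional string recording how the training set was
#'   generated.
#' @return An object of class `pca_feature_basis`.
#' @export
fit_pca_basis <- function(train_traces, n_components = 10L,
                          provenance = "prior-predictive simulations") {
  basis <- lapply(train_traces, function(X) {
    X <- as.matrix(X)
    if (nrow(X) < 50L) stop("need >= 50 training simulations per protocol", call. = FALSE)
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu, "-")
    sv <- svd(Xc, nu = 0, nv = n_components)
    if (sv$d[n_components] <= 1e-10 * sv$d[1L]) {
      stop("rank-deficient training matrix for PCA basis", call. = FALSE)
    }
    expl <- sum(sv$d[seq_len(n_components)]^2) / sum(sv$d^2)
    list(loadings = sv$v, mean = mu, explained = expl)
  })
  structure(list(basis = basis, n_components = as.integer(n_components),
                 provenance = provenance),
            class = "pca_feature_basis")
}

#' Project current traces onto the summary-feature basis
#'
#' @param traces Named list of traces (as from [simulate_channel()]),
#'   matching the basis protocols.
#' @param basis A `pca_feature_basis`.
#' @return Numeric feature vector of length `5 * (n_components + 1)`.
#' @export
channel_features <- function(traces, basis) {
  stopifnot(inherits(basis, "pca_feature_basis"))
  out <- lapply(names(basis$basis), function(pn) {
    b <- basis$basis[[pn]]
    y <- as.numeric(traces[[pn]])
    X <- cbind(b$loadings, 1)
    as.numeric(qr.solve(X, y))
  })
  unlist(out)
}

#' Build the Omnimodel feature basis from prior-predictive simulations
#'
#' Convenience wrapper: simulates `n_train` prior draws through all
#' protocols and fits the PCA basis.
#'
#' @param n_train Number of training simulations (>= 50).
#' @param seed Integer seed.
#' @param protocols Protocol list.
#' @return A `pca_feature_basis`.
#' @export
omnimodel_pca_basis <- function(n_train = 100L, seed = 1L,
                                protocols = clamp_protocols()) {
  prior <- omnimodel_prior()
  theta <- prior_sample(prior, n_train, seed = child_seed(seed, 0L))
  per_proto <- lapply(protocols, function(p) {
    matrix(NA_real_, n_train, length(simulate_current(theta[1, ], p,
                                                      seed = child_seed(seed, 1L))))
  })
  for (i in seq_len(n_train)) {
    set.seed(child_seed(seed, 10L + i))
    tr <- simulate_channel(theta[i, ], protocols)
    for (pn in names(protocols)) per_proto[[pn]][i, ] <- tr[[pn]]
  }
  fit_pca_basis(per_proto,
                provenance = sprintf("%d prior-predictive simulations (seed %d)",
                                     n_train, seed))
}
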