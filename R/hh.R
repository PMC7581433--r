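# Stochastic single-compartment Hodgkin-Huxley neuron: leak, transient
# Na+, delayed-rectifier K+, and slow (M-type) K+ currents with intrinsic
# Gaussian voltage noise.  Eight free parameters (four conductance
# densities, the adaptation time scale tau_max, the threshold shift V_T,
# the noise scale sigma, and the leak reversal E_l); reversal potentials
# are fixed at E_Na = 53 mV and E_K = -107 mV.  V_T and E_l are sampled as
# positive magnitudes and applied with negative sign, matching the prior
# box ranges.

hh_par_names <- c("gbar_Na", "gbar_K", "g_leak", "gbar_M", "tau_max",
                  "V_T", "sigma", "E_leak")

#' Uniform prior over the eight Hodgkin-Huxley parameters
#'
#' Conductance densities in mS/cm^2, tau_max in ms, V_T and E_leak as
#' positive magnitudes in mV (applied with negative sign in the
#' equations), sigma in mV ms^{-1/2}-equivalent current units.
#'
#' @return A `prior_box` over 8 dimensions.
#' @export
hh_prior <- function() {
  prior_box(
    lower = c(0.5, 1e-4, 1e-4, 1e-4, 50, 40, 1e-4, 35),
    upper = c(80, 15, 0.6, 0.6, 3000, 90, 0.15, 100),
    names = hh_par_names
  )
}

#' Default current-clamp protocol
#'
#' A square depolarizing pulse: 120 ms total, current on from 10 to 90 ms.
#'
#' @param t_total,t_on,t_off Window and pulse times (ms).
#' @param i_amp Injected current density (uA/cm^2).
#' @param dt Integration step (ms, <= 0.05).
#' @param store_every Keep every n-th voltage sample.
#' @return A list protocol specification.
#' @export
hh_protocol <- function(t_total = 120, t_on = 10, t_off = 90, i_amp = 2,
                        dt = 0.025, store_every = 2L) {
  stopifnot(dt <= 0.05, t_on < t_off, t_off <= t_total)
  list(t_total = t_total, t_on = t_on, t_off = t_off, i_amp = i_amp,
       dt = dt, store_every = as.integer(store_every))
}

#' Simulate the stochastic Hodgkin-Huxley neuron
#'
#' Forward-Euler voltage update with exponential-Euler gating; per-step
#' Gaussian noise is scaled by `1/sqrt(dt)` so sigma has consistent units
#' across step sizes.  Numerical blow-up (|V| > 1000 mV) marks the trace
#' invalid (`NA` tail).
#'
#' @param params Parameter vector in the order of [hh_prior()].
#' @param protocol A protocol from [hh_protocol()].
#' @param seed Optional integer seed (noise reproducibility).
#' @param e_na,e_k Fixed reversal potentials (mV).
#' @return A list of class `hh_trace` with `t` (ms), `v` (mV), and the
#'   protocol.
#' @export
simulate_hh <- function(params, protocol = hh_protocol(), seed = NULL,
                        e_na = 53, e_k = -107) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(length(params) == 8L)
  v <- hh_trace_cpp(as.numeric(params), protocol$dt, protocol$t_total,
                    protocol$t_on, protocol$t_off, protocol$i_amp,
                    protocol$store_every, e_na, e_k)
  structure(list(
    t = (seq_along(v) - 1L) * protocol$dt * protocol$store_every,
    v = as.numeric(v),
    protocol = protocol,
    valid = all(is.finite(v))
  ), class = "hh_trace")
}

#' Detect spikes by upward threshold crossing
#'
#' @param t Time vector (ms).
#' @param v Voltage vector (mV).
#' @param threshold Crossing threshold (mV, default -20).
#' @param refractory Minimum separation between detected spikes (ms).
#' @param mode `"crossing"` (upward crossings) or `"peak"` (local maxima
#'   above threshold).
#' @return Numeric vector of spike times.
#' @export
detect_spikes <- function(t, v, threshold = -20, refractory = 1,
                          mode = c("crossing", "peak")) {
  mode <- match.arg(mode)
  n <- length(v)
  if (n < 3L) return(numeric(0))
  idx <- if (mode == "crossing") {
    which(v[-1L] >= threshold & v[-n] < threshold) + 1L
  } else {
    which(v[2:(n - 1L)] > threshold &
          v[2:(n - 1L)] >= v[1:(n - 2L)] &
          v[2:(n - 1L)] >= v[3:n]) + 1L
  }
  if (length(idx) == 0L) return(numeric(0))
  times <- t[idx]
  keep <- times[1L]
  for (tt in times[-1L]) {
    if (tt - tail(keep, 1L) >= refractory) keep <- c(keep, tt)
  }
  keep
}

#' Seven voltage summary features
#'
#' Spike count (upward crossings of the detection threshold during the
#' stimulus window), mean and SD of the resting potential (pre-stimulus
#' window), and the first four moments (mean, SD, skewness, kurtosis) of
#' the voltage during the stimulus window.
#'
#' @param trace An `hh_trace` from [simulate_hh()].
#' @param threshold Spike-detection threshold (mV).
#' @param refractory Spike-detection refractory period (ms).
#' @return Named numeric vector of length 7 (`NA`s for invalid traces).
#' @export
hh_features <- function(trace, threshold = -20, refractory = 1) {
  p <- trace$protocol
  pre <- trace$t < p$t_on
  stim <- trace$t >= p$t_on & trace$t < p$t_off
  if (sum(pre) < 2L || sum(stim) < 2L) {
    stop("stimulus/rest windows shorter than 2 samples", call. = FALSE)
  }
  if (!trace$valid) {
    return(setNames(rep(NA_real_, 7L),
                    c("spike_count", "rest_mean", "rest_sd",
                      "m1", "m2", "m3", "m4")))
  }
  sp <- length(detect_spikes(trace$t[stim], trace$v[stim],
                             threshold = threshold, refractory = refractory))
  vr <- trace$v[pre]
  vs <- trace$v[stim]
  m1 <- mean(vs)
  s <- sd(vs)
  skew <- if (s > 0) mean((vs - m1)^3) / s^3 else 0
  kurt <- if (s > 0) mean((vs - m1)^4) / s^4 else 0
  c(spike_count = sp, rest_mean = mean(vr), rest_sd = sd(vr),
    m1 = m1, m2 = s, m3 = skew, m4 = kurt)
}

#' Simulator/extractor pair for SNPE on the Hodgkin-Huxley model
#'
#' @param protocol Current protocol.
#' @param feature_set Indices of features to keep (1 = spike count, then
#'   resting mean/SD, then the four stimulus-window moments), or a count
#'   `k` meaning the first `k` features.
#' @return List with `simulator(theta, seed)` and `extractor(raw)`.
#' @export
hh_model <- function(protocol = hh_protocol(), feature_set = 7L) {
  idx <- if (length(feature_set) == 1L) seq_len(feature_set) else feature_set
  list(
    simulator = function(theta, seed = NULL) simulate_hh(theta, protocol, seed = seed),
    extractor = function(raw) unname(hh_features(raw)[idx]),
    feature_names = c("spike_count", "rest_mean", "rest_sd",
                      "m1", "m2", "m3", "m4")[idx]
  )
}

#' Posterior inference for the Hodgkin-Huxley model
#'
#' Runs SNPE on a synthetic observation's features using a subset of 1, 4
#' or 7 voltage features, reproducing the constraint-tightening analysis
#' in which the posterior narrows as features are added.
#'
#' @param x_o Observed feature vector (already restricted to
#'   `feature_set`).
#' @param budget Total simulation budget (>= 500).
#' @param rounds SNPE rounds.
#' @param feature_set As in [hh_model()].
#' @param protocol Current protocol.
#' @param config Optional estimator config (default: two-layer MDN).
#' @param seed Integer seed.
#' @return An `snpe_posterior` over the 8 parameters.
#' @export
run_hh_inference <- function(x_o, budget = 2000L, rounds = 1L,
                             feature_set = 7L, protocol = hh_protocol(),
                             config = NULL, seed = 1L) {
  if (budget < 500L) stop("simulation budget below 500 is refused", call. = FALSE)
  mod <- hh_model(protocol, feature_set)
  stopifnot(length(x_o) == length(mod$feature_names))
  run_snpe(hh_prior(), mod$simulator, mod$extractor, x_o,
           config = config, rounds = rounds,
           n_per_round = budget %/% rounds, seed = seed)
}
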