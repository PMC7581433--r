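# Three-neuron model of the pyloric circuit in the crustacean
# stomatogastric ganglion: AB/PD (the electrically coupled pacemaker pair
# as one compartment), LP and PY.  Each neuron carries eight membrane
# currents (Na, CaT, CaS, A, KCa, Kd, H, leak) with intracellular calcium
# dynamics; seven graded inhibitory synapses connect the cells (fast
# glutamatergic and slow cholinergic).  The 31 free parameters are the 24
# maximal membrane conductances plus the 7 maximal synaptic conductances,
# the latter handled in log10 space throughout.

stg_neuron_names <- c("AB", "LP", "PY")
stg_current_names <- c("Na", "CaT", "CaS", "A", "KCa", "Kd", "H", "leak")
stg_synapse_names <- c("AB-LP", "PD-LP", "AB-PY", "PD-PY",
                       "LP-AB", "LP-PY", "PY-LP")
stg_synapse_glut <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)

#' Prior over the 31 pyloric-circuit parameters
#'
#' Box-uniform over the 24 maximal membrane conductances (mS/cm^2, ranges
#' per neuron and current) and log10-uniform over the 7 synaptic
#' conductances (0.01 to 1000 nS; AB-LP up to 10000 nS).  The synaptic
#' dimensions are expressed in log10(nS), the space in which they are
#' trained and analyzed.
#'
#' @return A `prior_box` over 31 dimensions.
#' @export
stg_prior <- function() {
  mem_low <- c(
    0, 0, 0, 0, 0, 25, 0, 0,         # AB/PD
    0, 0, 2, 10, 0, 0, 0, 0.01,      # LP
    0, 0, 0, 30, 0, 50, 0, 0)        # PY
  mem_high <- c(
    500, 7.5, 8, 60, 15, 150, 0.2, 0.01,
    200, 2.5, 12, 60, 10, 125, 0.06, 0.04,
    600, 12.5, 4, 60, 5, 150, 0.06, 0.04)
  syn_low <- rep(log10(0.01), 7)
  syn_high <- c(log10(10000), rep(log10(1000), 6))
  nm <- c(paste(rep(stg_neuron_names, each = 8), stg_current_names, sep = "_"),
          paste0("log10_g_", stg_synapse_names))
  prior_box(c(mem_low, syn_low), c(mem_high, syn_high), names = nm)
}

#' Graded synapse activation curve and time constant
#'
#' \eqn{\bar s(V_{pre}) = 1/(1+\exp((V_{th}-V_{pre})/\delta))} with
#' \eqn{V_{th} = -35} mV, \eqn{\delta = 5} mV, and
#' \eqn{\tau_s = (1-\bar s)/k_-} with dissociation rate
#' \eqn{k_- = 1/40} ms (glutamatergic) or \eqn{1/100} ms (cholinergic).
#'
#' @param v_pre Presynaptic membrane potential (mV), vectorized.
#' @param type `"glutamatergic"` or `"cholinergic"`.
#' @return List with `sbar` and `tau_s` (ms).
#' @export
synapse_state <- function(v_pre, type = c("glutamatergic", "cholinergic")) {
  type <- match.arg(type)
  k_minus <- if (type == "glutamatergic") 1 / 40 else 1 / 100
  sbar <- 1 / (1 + exp((-35 - v_pre) / 5))
  list(sbar = sbar, tau_s = (1 - sbar) / k_minus)
}

#' Graded synaptic current
#'
#' \eqn{I_s = g_s\, s\, (V_{post} - E_s)}.
#'
#' @param g_s Maximal synaptic conductance.
#' @param s Activation in `[0, 1]`.
#' @param v_post Postsynaptic potential (mV).
#' @param e_s Synaptic reversal potential (mV, -70 glutamatergic / -80
#'   cholinergic).
#' @return Current (units follow `g_s`).
#' @export
synaptic_current <- function(g_s, s, v_post, e_s) {
  stopifnot(all(s >= 0 & s <= 1))
  g_s * s * (v_post - e_s)
}

#' Simulate the pyloric circuit
#'
#' Integrates the three-neuron network with per-step Gaussian voltage
#' noise of SD `noise_sd` mV ms^{-1/2} (scaled by sqrt(dt)).  Numerical
#' blow-up (|V| > 500 mV) marks the simulation invalid.
#'
#' @param params 31-vector in [stg_prior()] order (synapses in
#'   log10(nS)).
#' @param duration Simulated time in ms (>= 2000).
#' @param dt Integration step in ms (default 0.025).
#' @param seed Optional integer seed.
#' @param noise_sd Voltage noise SD (mV ms^-0.5); 0 disables noise.
#' @param store_every Keep every n-th sample (default 4, i.e. 0.1 ms).
#' @return A list of class `stg_trace` with `t` (ms), `v` (3 x n matrix,
#'   rows AB/PD, LP, PY) and `valid`.
#' @export
simulate_stg <- function(params, duration = 3000, dt = 0.025, seed = NULL,
                         noise_sd = 0.001, store_every = 4L) {
  stopifnot(length(params) == 31L, duration >= 2000)
  if (!is.null(seed)) set.seed(as.integer(seed))
  gmem <- matrix(params[1:24], nrow = 3L, byrow = TRUE)
  gsyn <- 10^params[25:31]
  v <- stg_trace_cpp(gmem, gsyn, dt, duration, noise_sd,
                     as.integer(store_every))
  structure(list(
    t = (seq_len(ncol(v)) - 1L) * dt * store_every,
    v = v,
    dt_store = dt * store_every,
    valid = all(is.finite(v))
  ), class = "stg_trace")
}

# Two-threshold gap classifier: split inter-spike intervals into
# within-burst and between-burst gaps.  A burst is >= 2 spikes whose
# internal gaps are below 0.5 * (mean between-burst gap); the threshold is
# found by fixed-point iteration from the mean ISI.
segment_bursts <- function(spike_times, max_iter = 25L) {
  ns <- length(spike_times)
  if (ns < 2L) return(NULL)
  isi <- diff(spike_times)
  thr <- mean(isi)
  for (i in seq_len(max_iter)) {
    inter <- isi[isi >= thr]
    if (length(inter) == 0L) return(NULL)   # no between-burst gaps found
    new_thr <- 0.5 * mean(inter)
    if (abs(new_thr - thr) < 1e-9) break
    thr <- new_thr
  }
  grp <- cumsum(c(1, as.integer(isi >= thr)))
  starts <- tapply(spike_times, grp, min)
  ends <- tapply(spike_times, grp, max)
  sizes <- tapply(spike_times, grp, length)
  keep <- sizes >= 2L
  if (!any(keep)) return(NULL)
  data.frame(start = as.numeric(starts[keep]), end = as.numeric(ends[keep]),
             n_spikes = as.integer(sizes[keep]))
}

#' Names of the 18 pyloric summary features
#' @return Character vector of length 18.
#' @export
pyloric_feature_names <- function() {
  c("period",
    "burst_dur_AB", "burst_dur_LP", "burst_dur_PY",
    "gap_ABend_LPstart", "gap_LPend_PYstart",
    "delay_ABstart_LPstart", "delay_LPstart_PYstart",
    "duty_AB", "duty_LP", "duty_PY",
    "phasegap_ABend_LPstart", "phasegap_LPend_PYstart",
    "phase_LP", "phase_PY",
    "plateau_AB", "plateau_LP", "plateau_PY")
}

# longest consecutive duration above a voltage level, floored at `floor_ms`
max_plateau <- function(v, dt_store, level = -30, floor_ms = 5) {
  above <- v > level
  if (!any(above)) return(floor_ms)
  r <- rle(above)
  best <- max(r$lengths[r$values]) * dt_store
  max(best, floor_ms)
}

#' Extract the 18 pyloric rhythm features
#'
#' Spike detection (local maxima above `threshold`), two-threshold burst
#' segmentation, then the 15 cycle features of the triphasic rhythm: cycle
#' period, per-neuron burst durations, end-to-start gaps and start-to-start
#' delays between AB/PD and LP and between LP and PY, duty cycles, phase
#' gaps, and LP/PY start phases.  These are only defined when every neuron
#' bursts rhythmically; otherwise the rhythm features are `NA` and the
#' result is flagged invalid.  The 3 plateau features (longest time above
#' -30 mV, floored at 5 ms) are always computed.
#'
#' @param sim An `stg_trace` from [simulate_stg()].
#' @param threshold Spike-detection threshold (mV).
#' @param transient Initial transient to discard (ms).
#' @return Named numeric vector of length 18 with attribute `valid`.
#' @export
pyloric_features <- function(sim, threshold = -20, transient = 1000) {
  stopifnot(inherits(sim, "stg_trace"))
  nm <- pyloric_feature_names()
  out <- setNames(rep(NA_real_, 18L), nm)
  keep <- sim$t >= transient
  if (sum(keep) < 10L || !sim$valid) {
    out[16:18] <- 5
    attr(out, "valid") <- FALSE
    return(out)
  }
  tt <- sim$t[keep]
  V <- sim$v[, keep, drop = FALSE]
  for (i in 1:3) {
    out[15L + i] <- max_plateau(V[i, ], sim$dt_store)
  }
  bursts <- lapply(1:3, function(i) {
    sp <- detect_spikes(tt, V[i, ], threshold = threshold, refractory = 2,
                        mode = "peak")
    segment_bursts(sp)
  })
  if (any(vapply(bursts, function(b) is.null(b) || nrow(b) < 2L, logical(1)))) {
    out[16:18] <- pmax(out[16:18], 5)
    attr(out, "valid") <- FALSE
    return(out)
  }
  ab <- bursts[[1L]]; lp <- bursts[[2L]]; py <- bursts[[3L]]
  period <- mean(diff(ab$start))
  # per-AB-cycle matching of LP and PY bursts
  cyc <- list()
  for (ci in seq_len(nrow(ab) - 1L)) {
    w0 <- ab$start[ci]; w1 <- ab$start[ci + 1L]
    li <- which(lp$start >= w0 & lp$start < w1)
    pi_ <- which(py$start >= w0 & py$start < w1)
    if (length(li) == 0L || length(pi_) == 0L) next
    li <- li[1L]; pi_ <- pi_[1L]
    cyc[[length(cyc) + 1L]] <- c(
      ab_start = w0, ab_end = ab$end[ci],
      lp_start = lp$start[li], lp_end = lp$end[li],
      py_start = py$start[pi_], py_end = py$end[pi_])
  }
  if (length(cyc) == 0L) {
    attr(out, "valid") <- FALSE
    return(out)
  }
  M <- do.call(rbind, cyc)
  out["period"] <- period
  out["burst_dur_AB"] <- mean(ab$end - ab$start)
  out["burst_dur_LP"] <- mean(lp$end - lp$start)
  out["burst_dur_PY"] <- mean(py$end - py$start)
  out["gap_ABend_LPstart"] <- mean(M[, "lp_start"] - M[, "ab_end"])
  out["gap_LPend_PYstart"] <- mean(M[, "py_start"] - M[, "lp_end"])
  out["delay_ABstart_LPstart"] <- mean(M[, "lp_start"] - M[, "ab_start"])
  out["delay_LPstart_PYstart"] <- mean(M[, "py_start"] - M[, "lp_start"])
  out["duty_AB"] <- out["burst_dur_AB"] / period
  out["duty_LP"] <- out["burst_dur_LP"] / period
  out["duty_PY"] <- out["burst_dur_PY"] / period
  out["phasegap_ABend_LPstart"] <- out["gap_ABend_LPstart"] / period
  out["phasegap_LPend_PYstart"] <- out["gap_LPend_PYstart"] / period
  out["phase_LP"] <- out["delay_ABstart_LPstart"] / period
  out["phase_PY"] <- mean(M[, "py_start"] - M[, "ab_start"]) / period
  attr(out, "valid") <- TRUE
  out
}

#' Simulator/extractor pair for SNPE on the pyloric circuit
#'
#' Features are converted to seconds (durations) for training; invalid
#' (non-bursting) simulations yield `NA` features and are flagged by the
#' simulation table machinery.
#'
#' @param duration,dt,noise_sd,store_every Passed to [simulate_stg()].
#' @return List with `simulator` and `extractor` functions.
#' @export
stg_model <- function(duration = 3000, dt = 0.025, noise_sd = 0.001,
                      store_every = 4L) {
  list(
    simulator = function(theta, seed = NULL)
      simulate_stg(theta, duration = duration, dt = dt, seed = seed,
                   noise_sd = noise_sd, store_every = store_every),
    extractor = function(raw) {
      f <- pyloric_features(raw)
      # report durations in seconds, phases/duty cycles dimensionless
      f[c(1:8, 16:18)] <- f[c(1:8, 16:18)] / 1000
      unname(f)
    },
    feature_names = pyloric_feature_names()
  )
}
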