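# Temporal linear-nonlinear encoding model: a Bernoulli GLM whose
# parameters are a length-9 linear filter plus a bias.  Within each of
# T = 100 time bins, a spike is emitted with probability
# sigmoid(v_i' f + beta), where v_i collects the white-noise input over
# the 9 bins up to and including bin i.  The spike count N together with
# the spike-triggered sum V z is sufficient for this model, so (N, STA)
# is used as the summary-feature vector.

#' White-noise design matrix for the temporal GLM
#'
#' @param T_bins Number of time bins (default 100).
#' @param n_taps Filter length (default 9).
#' @param seed Optional integer seed for the stimulus.
#' @return A `T_bins` x `n_taps` design matrix whose row `i` is the
#'   stimulus over bins `i - n_taps + 1 ... i` (i.i.d. standard normal).
#' @export
glm_design <- function(T_bins = 100L, n_taps = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- rnorm(T_bins + n_taps - 1L)
  V <- matrix(0, T_bins, n_taps)
  for (i in seq_len(T_bins)) V[i, ] <- u[i:(i + n_taps - 1L)]
  V
}

#' Second-difference smoothness operator and prior covariance
#'
#' Builds the full-rank operator `F` whose interior rows are second
#' differences (the first and last rows pin the endpoints so that `F'F`
#' is invertible) and the covariance `Sigma = sigma^2 (F'F)^{-1}` that
#' penalizes rough filters.
#'
#' @param n Filter length.
#' @param sigma Prior scale.
#' @return List with `F`, `Sigma` and `sigma`.
#' @export
smoothness_prior <- function(n, sigma = 1) {
  F <- matrix(0, n, n)
  F[1, 1] <- 1
  if (n >= 2) F[n, n] <- 1
  if (n >= 3) {
    for (i in 2:(n - 1L)) { F[i, i - 1L] <- 1; F[i, i] <- -2; F[i, i + 1L] <- 1 }
  }
  FtF <- crossprod(F)
  Sigma <- sigma^2 * solve(FtF)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(F = F, Sigma = Sigma, sigma = sigma)
}

#' Gaussian prior for the temporal GLM parameters (bias, filter)
#'
#' The 10-dimensional parameter vector is `(beta, f_1, ..., f_9)`.  The
#' filter block carries the second-difference smoothness covariance; the
#' bias is independent with variance `beta_var`.
#'
#' @param sigma Smoothness scale for the filter.
#' @param beta_var Prior variance of the bias.
#' @param n_taps Filter length.
#' @return A `prior_gaussian` over `n_taps + 1` dimensions.
#' @export
glm_temporal_prior <- function(sigma = 0.5, beta_var = 1, n_taps = 9L) {
  sp <- smoothness_prior(n_taps, sigma)
  Sigma <- matrix(0, n_taps + 1L, n_taps + 1L)
  Sigma[1, 1] <- beta_var
  Sigma[-1, -1] <- sp$Sigma
  prior_gaussian(rep(0, n_taps + 1L), Sigma,
                 names = c("beta", paste0("f", seq_len(n_taps))))
}

#' Simulate the temporal Bernoulli GLM
#'
#' @param params Numeric vector `(beta, f_1..f_9)`.
#' @param design Design matrix from [glm_design()].
#' @param seed Optional integer seed.
#' @return Integer 0/1 spike vector of length `nrow(design)`.
#' @export
simulate_temporal_glm <- function(params, design, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  check_finite(design, "design matrix")
  beta <- params[1L]
  f <- params[-1L]
  p <- sigmoid(as.numeric(design %*% f) + beta)
  rbinom(length(p), 1L, p)
}

#' Spike count and spike-triggered average
#'
#' @param z 0/1 spike vector.
#' @param design Design matrix (rows aligned with `z`).
#' @return Numeric vector `(N, STA)` of length `ncol(design) + 1`; when no
#'   spike occurred the STA is the zero vector and the result carries
#'   `attr(, "valid") = FALSE`.
#' @export
sta_summary <- function(z, design) {
  stopifnot(length(z) == nrow(design))
  N <- sum(z)
  if (N == 0) {
    out <- c(0, numeric(ncol(design)))
    attr(out, "valid") <- FALSE
    return(out)
  }
  sta <- as.numeric(crossprod(design, z)) / N
  out <- c(N, sta)
  attr(out, "valid") <- TRUE
  out
}

#' Log-posterior of the temporal GLM (tractable reference)
#'
#' Bernoulli log-likelihood plus the Gaussian smoothness prior; used by
#' the MCMC reference sampler against which SNPE and the ABC baselines are
#' scored.
#'
#' @param theta Parameter vector or row matrix `(beta, f)`.
#' @param z Observed spike vector.
#' @param design Design matrix.
#' @param prior A `prior_gaussian` as from [glm_temporal_prior()].
#' @return Numeric vector of unnormalized log-posterior values.
#' @export
glm_log_posterior <- function(theta, z, design, prior) {
  theta <- as_row_matrix(theta)
  eta <- design %*% t(theta[, -1L, drop = FALSE])
  eta <- sweep(eta, 2L, theta[, 1L], "+")
  # sum_i [ z_i eta_i - log(1 + exp(eta_i)) ], columns = parameter vectors
  ll <- colSums(z * eta) - colSums(softplus(eta))
  ll + prior_log_density(prior, theta)
}
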