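# Spatial receptive-field encoding model: a Poisson GLM whose linear
# filter is constrained to be a Gabor function of 8 parameters (gain,
# spatial frequency, aspect ratio, octave bandwidth, phase, orientation,
# and 2-D location) plus a bias.  Bounded parameters are handled through
# log / generalized-logit transforms so inference can run in an
# unconstrained space.

gabor_par_names <- c("gain", "freq", "aspect", "width", "phase", "angle",
                     "x", "y", "beta")

# envelope width from spatial frequency f and octave bandwidth w
gabor_sigma <- function(f, w) {
  sqrt(2 * log(2)) / (2 * pi * f) * (2^w + 1) / (2^w - 1)
}

#' Square coordinate grid spanning the stimulated area
#'
#' @param n Pixels per side.
#' @return List with matrices `gx`, `gy` of coordinates in `[-1, 1]`.
#' @export
gabor_grid <- function(n = 41L) {
  g <- seq(-1, 1, length.out = n)
  list(gx = matrix(g, n, n), gy = matrix(g, n, n, byrow = TRUE), n = n)
}

#' Evaluate a Gabor receptive field on a grid
#'
#' The filter is a cosine carrier under a rotated anisotropic Gaussian
#' envelope,
#' \deqn{h = g \exp(-(x'^2 + r^2 y'^2)/(2\sigma^2)) \cos(2\pi f x' - \phi)}
#' with the rotated coordinates
#' `x' = (gx - x) cos(psi) - (gy - y) sin(psi)`,
#' `y' = (gx - x) sin(psi) + (gy - y) cos(psi)`,
#' and envelope width `sigma` derived from the spatial frequency and the
#' octave bandwidth `w` via
#' \eqn{\sigma = \sqrt{2\log 2}/(2\pi f) \cdot (2^w+1)/(2^w-1)}.
#'
#' @param params Named numeric vector with entries `gain, freq, aspect,
#'   width, phase, angle, x, y` (a trailing `beta` is ignored here).
#' @param grid A grid from [gabor_grid()].
#' @return Matrix of filter values with the grid's dimensions.
#' @export
gabor_filter <- function(params, grid = gabor_grid()) {
  if (is.null(names(params))) {
    names(params) <- gabor_par_names[seq_along(params)]
  }
  p <- as.list(params[gabor_par_names[1:8]])
  xr <- (grid$gx - p$x) * cos(p$angle) - (grid$gy - p$y) * sin(p$angle)
  yr <- (grid$gx - p$x) * sin(p$angle) + (grid$gy - p$y) * cos(p$angle)
  sg <- gabor_sigma(p$freq, p$width)
  p$gain * exp(-(xr^2 + p$aspect^2 * yr^2) / (2 * sg^2)) *
    cos(2 * pi * p$freq * xr - p$phase)
}

#' Transforms between natural and unconstrained Gabor parameters
#'
#' Positive parameters (gain, frequency, aspect ratio, width) are
#' log-transformed; interval-bounded ones use the generalized logit
#' \eqn{l_{a,b}}: phase on `(0, pi)`, angle on `(0, 2 pi)`, location on
#' `(-1, 1)`.  The bias is untransformed.
#'
#' @return A transform set from [make_transforms()] over the 9-vector
#'   `(gain, freq, aspect, width, phase, angle, x, y, beta)`.
#' @export
gabor_transforms <- function() {
  make_transforms(
    kinds = c("log", "log", "log", "log", "logit", "logit", "logit", "logit",
              "identity"),
    a = c(NA, NA, NA, NA, 0, 0, -1, -1, NA),
    b = c(NA, NA, NA, NA, pi, 2 * pi, 1, 1, NA)
  )
}

#' Map Gabor parameters to the unconstrained space (and back)
#'
#' @param params Natural-space parameter vector (length 9, ordered as in
#'   [gabor_transforms()]).
#' @return `transform_gabor`: unconstrained 9-vector.
#'   `untransform_gabor`: natural-space 9-vector.
#' @export
transform_gabor <- function(params) {
  tr <- gabor_transforms()
  eta <- as.numeric(tr$forward(params))
  if (!all(is.finite(eta))) stop("parameters on or outside their bounds", call. = FALSE)
  setNames(eta, gabor_par_names)
}

#' @rdname transform_gabor
#' @param eta Unconstrained 9-vector.
#' @export
untransform_gabor <- function(eta) {
  tr <- gabor_transforms()
  setNames(as.numeric(tr$inverse(eta)), gabor_par_names)
}

#' Prior over Gabor parameters
#'
#' Zero-mean Gaussian on the transformed parameters with standard
#' deviations `(0.5, 0.5, 0.5, 0.5, 1.9, 1.78, 1.78, 1.78)` (a logit-scale
#' SD near 1.78 is close to uniform on the natural interval), and a
#' Gaussian `N(-0.57, 1.63)` on the untransformed bias, which approximates
#' a unit-rate exponential prior on the baseline firing rate `exp(beta)`.
#'
#' @param space `"transformed"` (prior over the unconstrained 9-vector,
#'   the space in which inference runs) or `"natural"` (transformed prior
#'   pushed through the inverse maps, Jacobian included).
#' @return A `prior` object.
#' @export
gabor_prior <- function(space = c("transformed", "natural")) {
  space <- match.arg(space)
  sds <- c(0.5, 0.5, 0.5, 0.5, 1.9, 1.78, 1.78, 1.78)
  mean <- c(rep(0, 8), -0.57)
  vars <- c(sds^2, 1.63)
  base <- prior_gaussian(mean, vars, names = gabor_par_names)
  if (space == "transformed") base else
    prior_transformed(base, gabor_transforms(), names = gabor_par_names)
}

#' Simulate the Gabor Poisson GLM
#'
#' Spike counts per bin follow `Poisson(exp(v_i' h + beta))` where `v_i`
#' is the vectorized white-noise frame at bin `i`.
#'
#' @param params Natural-space parameter vector (length 9).
#' @param movie `T x n_pixels` stimulus matrix (rows = frames).
#' @param grid Grid matching `n_pixels`.
#' @param seed Optional integer seed.
#' @param rate_cap Rates above this mark the simulation invalid (overflow
#'   guard).
#' @return Integer vector of spike counts per bin.
#' @export
simulate_gabor_glm <- function(params, movie, grid = gabor_grid(16L),
                               seed = NULL, rate_cap = 1e6) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  check_finite(movie, "stimulus movie")
  h <- as.numeric(gabor_filter(params, grid))
  stopifnot(ncol(movie) == length(h))
  lam <- exp(as.numeric(movie %*% h) + params[9L])
  if (any(!is.finite(lam)) || any(lam > rate_cap)) {
    stop("firing rate overflow", call. = FALSE)
  }
  rpois(length(lam), lam)
}

#' Summary features for the Gabor GLM
#'
#' @param z Spike-count vector.
#' @param movie Stimulus matrix aligned with `z`.
#' @return `(N, STA)` with the pixelwise spike-triggered average;
#'   zero-spike simulations return zeros flagged via `attr(, "valid")`.
#' @export
gabor_summary <- function(z, movie) {
  sta_summary(z, movie)
}
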