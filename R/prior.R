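# Prior specifications: box-uniform and Gaussian priors, optionally
# composed with per-dimension transforms (log / generalized logit) so that
# inference can run in an unconstrained space while the simulator receives
# natural-space parameters.

#' Box-uniform prior
#'
#' @param lower,upper Numeric vectors of finite bounds (equal length).
#' @param names Optional parameter names.
#' @return A `prior_box` object (also of class `prior`).
#' @export
prior_box <- function(lower, upper, names = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 names = names %||% paste0("theta_", seq_along(lower))),
            class = c("prior_box", "prior"))
}

#' Multivariate Gaussian prior
#'
#' @param mean Mean vector.
#' @param cov Covariance matrix (or vector of variances).
#' @param names Optional parameter names.
#' @return A `prior_gaussian` object (also of class `prior`).
#' @export
prior_gaussian <- function(mean, cov, names = NULL) {
  if (!is.matrix(cov)) cov <- diag(cov, length(mean))
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  ch <- chol(cov)   # errors if not positive definite
  structure(list(mean = as.numeric(mean), cov = cov, chol = ch,
                 names = names %||% paste0("theta_", seq_along(mean))),
            class = c("prior_gaussian", "prior"))
}

#' Push a prior defined on transformed parameters into natural space
#'
#' Given a prior on the unconstrained (transformed) parameters and a
#' transform set, returns a `prior` object over natural-space parameters:
#' sampling draws in transformed space and back-transforms; the natural
#' density includes the Jacobian of the transform.
#'
#' @param base_prior Prior on transformed parameters eta.
#' @param transforms Result of [make_transforms()].
#' @param names Optional natural-parameter names.
#' @return A `prior_transformed` object (also of class `prior`).
#' @export
prior_transformed <- function(base_prior, transforms, names = NULL) {
  structure(list(base = base_prior, tr = transforms,
                 names = names %||% base_prior$names),
            class = c("prior_transformed", "prior"))
}

#' @export
print.prior <- function(x, ...) {
  cat(sprintf("<%s> dimension %d\n", class(x)[1L], prior_dim(x)))
  invisible(x)
}

#' Dimensionality of a prior
#' @param prior A `prior` object.
#' @return Integer dimension.
#' @export
prior_dim <- function(prior) UseMethod("prior_dim")

#' @export
prior_dim.prior_box <- function(prior) length(prior$lower)

#' @export
prior_dim.prior_gaussian <- function(prior) length(prior$mean)

#' @export
prior_dim.prior_transformed <- function(prior) prior_dim(prior$base)

#' Draw samples from a prior
#' @param prior A `prior` object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An `n` x `d` matrix.
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  UseMethod("prior_sample")
}

#' @export
prior_sample.prior_box <- function(prior, n, seed = NULL) {
  d <- prior_dim(prior)
  U <- matrix(runif(n * d), n, d)
  out <- sweep(sweep(U, 2L, prior$upper - prior$lower, "*"), 2L, prior$lower, "+")
  colnames(out) <- prior$names
  out
}

#' @export
prior_sample.prior_gaussian <- function(prior, n, seed = NULL) {
  d <- prior_dim(prior)
  Z <- matrix(rnorm(n * d), n, d)
  out <- sweep(Z %*% prior$chol, 2L, prior$mean, "+")
  colnames(out) <- prior$names
  out
}

#' @export
prior_sample.prior_transformed <- function(prior, n, seed = NULL) {
  out <- prior$tr$inverse(prior_sample(prior$base, n))
  colnames(out) <- prior$names
  out
}

#' Prior log-density
#' @inheritParams prior_sample
#' @param theta Parameter vector or matrix of row vectors.
#' @return Numeric vector of log-densities (`-Inf` outside support).
#' @export
prior_log_density <- function(prior, theta) UseMethod("prior_log_density")

#' @export
prior_log_density.prior_box <- function(prior, theta) {
  theta <- as_row_matrix(theta)
  inside <- prior_in_support(prior, theta)
  ld <- rep(-Inf, nrow(theta))
  ld[inside] <- -sum(log(prior$upper - prior$lower))
  ld
}

#' @export
prior_log_density.prior_gaussian <- function(prior, theta) {
  theta <- as_row_matrix(theta)
  d <- length(prior$mean)
  dev <- sweep(theta, 2L, prior$mean, "-")
  y <- t(backsolve(prior$chol, t(dev), transpose = TRUE))
  -0.5 * d * log(2 * pi) - sum(log(diag(prior$chol))) - 0.5 * rowSums(y^2)
}

#' @export
prior_log_density.prior_transformed <- function(prior, theta) {
  theta <- as_row_matrix(theta)
  inside <- prior_in_support(prior, theta)
  ld <- rep(-Inf, nrow(theta))
  if (any(inside)) {
    th <- theta[inside, , drop = FALSE]
    eta <- prior$tr$forward(th)
    ld[inside] <- prior_log_density(prior$base, eta) + prior$tr$log_jacobian(th)
  }
  ld
}

#' Support membership test
#' @inheritParams prior_log_density
#' @return Logical vector, one entry per row of `theta`.
#' @export
prior_in_support <- function(prior, theta) UseMethod("prior_in_support")

#' @export
prior_in_support.prior_box <- function(prior, theta) {
  theta <- as_row_matrix(theta)
  rowSums(sweep(theta, 2L, prior$lower, "<") |
          sweep(theta, 2L, prior$upper, ">")) == 0L
}

#' @export
prior_in_support.prior_gaussian <- function(prior, theta) {
  rep(TRUE, nrow(as_row_matrix(theta)))
}

#' @export
prior_in_support.prior_transformed <- function(prior, theta) {
  theta <- as_row_matrix(theta)
  tr <- prior$tr
  ok <- rep(TRUE, nrow(theta))
  for (j in seq_along(tr$kinds)) {
    ok <- ok & switch(tr$kinds[j],
      identity = TRUE,
      log = theta[, j] > 0,
      logit = theta[, j] > tr$a[j] & theta[, j] < tr$b[j])
  }
  ok
}

# ---- per-dimension parameter transforms ---------------------------------

#' Per-dimension parameter transforms between natural and unconstrained space
#'
#' Builds forward (natural -> unconstrained) and inverse maps from a vector
#' of transform tags: `"identity"`, `"log"` (for positive parameters) or
#' `"logit"` (generalized logit \eqn{l_{a,b}(X) = \log((X-a)/(b-X))} for
#' parameters bounded in `(a, b)`).
#'
#' @param kinds Character vector of tags, one per dimension.
#' @param a,b Lower/upper bounds for `"logit"` dimensions (ignored
#'   elsewhere).
#' @return A list with functions `forward(theta)`, `inverse(eta)` and
#'   `log_jacobian(theta)` (log |d eta / d theta|, summed over dimensions),
#'   each accepting vectors or row matrices.
#' @export
make_transforms <- function(kinds, a = NULL, b = NULL) {
  stopifnot(all(kinds %in% c("identity", "log", "logit")))
  d <- length(kinds)
  a <- a %||% rep(NA_real_, d); b <- b %||% rep(NA_real_, d)
  stopifnot(length(a) == d, length(b) == d)
  fwd1 <- function(x, k, ai, bi) switch(k,
    identity = x,
    log = log(x),
    logit = log((x - ai) / (bi - x)))
  inv1 <- function(e, k, ai, bi) switch(k,
    identity = e,
    log = exp(e),
    logit = ai + (bi - ai) * sigmoid(e))
  lj1 <- function(x, k, ai, bi) switch(k,
    identity = 0 * x,
    log = -log(x),
    logit = log(bi - ai) - log(x - ai) - log(bi - x))
  apply_cols <- function(f, M) {
    M <- as_row_matrix(M)
    out <- M
    for (j in seq_len(d)) out[, j] <- f(M[, j], kinds[j], a[j], b[j])
    out
  }
  list(
    kinds = kinds, a = a, b = b,
    forward = function(theta) apply_cols(fwd1, theta),
    inverse = function(eta) apply_cols(inv1, eta),
    log_jacobian = function(theta) rowSums(apply_cols(lj1, theta))
  )
}
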