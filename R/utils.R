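# Internal numerical helpers shared across the package.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(rowSums(exp(X[ok, , drop = FALSE] - m[ok])))
  }
  out
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

softplus_grad <- function(x) {
  1 / (1 + exp(-x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Deterministically derive a child seed from a parent seed
#'
#' One global seed is expanded into per-component seeds (simulation,
#' training, sampling, ...) through a counter-based linear scheme, so that
#' every source of randomness in a run is reproducible from a single
#' integer while different components still receive decorrelated streams.
#'
#' @param seed Integer parent seed.
#' @param index Nonnegative integer counter identifying the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' child_seed(42, 0)
#' child_seed(42, 1)
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) %% 2147483647 + 1000003 * (as.double(index) + 1)) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

# coerce to numeric matrix with n rows (vectors become 1-row matrices)
as_row_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(x, nrow = 1L)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
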