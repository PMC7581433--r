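# Posterior-geometry tools: conditional distributions and correlations on
# evenly spaced grids, high-probability paths between disparate parameter
# sets (sinusoidal-basis curves minimizing a posterior-weighted path
# integral), and orthogonal perturbations via gradient projection.
#
# All tools operate on any "posterior-like" object: an `snpe_posterior`,
# an [analytic_posterior()], or a plain list with `log_prob` (and
# optionally `grad`, `sample`, `lower`, `upper`) entries.

geo_log_prob <- function(post, theta) {
  if (inherits(post, "snpe_posterior")) posterior_log_prob(post, theta)
  else if (is.function(post$log_prob)) post$log_prob(as_row_matrix(theta))
  else stop("object does not expose a log-density", call. = FALSE)
}

geo_grad <- function(post, theta) {
  if (inherits(post, "snpe_posterior")) return(posterior_log_prob_grad(post, theta))
  if (!is.null(post$grad)) return(as_row_matrix(post$grad(as_row_matrix(theta))))
  numeric_grad(function(th) geo_log_prob(post, th), theta)
}

geo_sample <- function(post, n, seed = NULL) {
  if (inherits(post, "snpe_posterior")) posterior_sample(post, n, seed = seed)
  else if (!is.null(post$sample)) { if (!is.null(seed)) set.seed(as.integer(seed)); post$sample(n) }
  else stop("object does not expose a sampler", call. = FALSE)
}

geo_bounds <- function(post, lower = NULL, upper = NULL) {
  if (!is.null(lower) && !is.null(upper)) return(list(lower = lower, upper = upper))
  if (inherits(post, "snpe_posterior") && inherits(post$prior, "prior_box")) {
    return(list(lower = post$prior$lower, upper = post$prior$upper))
  }
  if (!is.null(post$lower) && !is.null(post$upper)) {
    return(list(lower = post$lower, upper = post$upper))
  }
  stop("grid bounds required: supply `lower` and `upper`", call. = FALSE)
}

#' Analytic Gaussian posterior object (testbed and oracle)
#'
#' Wraps a multivariate Gaussian as a posterior-like object with analytic
#' log-density, gradient and sampler, for use with the geometry tools.
#'
#' @param mean Mean vector.
#' @param cov Covariance matrix.
#' @param lower,upper Optional box used as default grid bounds.
#' @return A list usable by [conditional_grid()], [optimize_path()], etc.
#' @export
analytic_posterior <- function(mean, cov, lower = NULL, upper = NULL) {
  if (!is.matrix(cov)) cov <- diag(cov, length(mean))
  ch <- chol(cov)
  P <- chol2inv(ch)       # precision matrix
  d <- length(mean)
  list(
    mean = mean, cov = cov, precision = P,
    lower = lower, upper = upper,
    log_prob = function(theta) {
      theta <- as_row_matrix(theta)
      dev <- sweep(theta, 2L, mean, "-")
      y <- t(backsolve(ch, t(dev), transpose = TRUE))
      -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * rowSums(y^2)
    },
    grad = function(theta) {
      theta <- as_row_matrix(theta)
      -sweep(theta, 2L, mean, "-") %*% P
    },
    sample = function(n) {
      sweep(matrix(rnorm(n * d), n, d) %*% ch, 2L, mean, "+")
    }
  )
}

# ---- conditional distributions ------------------------------------------

#' Conditional posterior density on an evenly spaced grid
#'
#' Fixes all parameters except one or two at `fixed` and evaluates the
#' posterior on an evenly spaced grid (default 50 points per dimension)
#' spanning the prior range of the free dimensions.  Density values are
#' normalized to sum to one.
#'
#' @param post Posterior-like object.
#' @param fixed Full-length parameter vector supplying the fixed values.
#' @param dims Indices of the 1 or 2 free dimensions.
#' @param lower,upper Grid bounds (full-length vectors; defaults from the
#'   posterior's prior box).
#' @param n_grid Points per free dimension.
#' @return An object of class `conditional_grid` with `axes`, `density`
#'   (vector or matrix), `dims`, `fixed`.
#' @export
conditional_grid <- function(post, fixed, dims, lower = NULL, upper = NULL,
                             n_grid = 50L) {
  stopifnot(length(dims) %in% 1:2)
  b <- geo_bounds(post, lower, upper)
  axes <- lapply(dims, function(j) seq(b$lower[j], b$upper[j], length.out = n_grid))
  if (length(dims) == 1L) {
    pts <- matrix(rep(fixed, each = n_grid), n_grid)
    pts[, dims] <- axes[[1L]]
  } else {
    gg <- expand.grid(a = axes[[1L]], b = axes[[2L]])
    pts <- matrix(rep(fixed, each = nrow(gg)), nrow(gg))
    pts[, dims[1L]] <- gg$a
    pts[, dims[2L]] <- gg$b
  }
  lp <- geo_log_prob(post, pts)
  m <- max(lp)
  dens <- if (is.finite(m)) exp(lp - m) else rep(0, length(lp))
  tot <- sum(dens)
  if (tot > 0) dens <- dens / tot
  if (length(dims) == 2L) dens <- matrix(dens, n_grid, n_grid)
  structure(list(axes = axes, density = dens, dims = dims, fixed = fixed,
                 n_grid = n_grid),
            class = "conditional_grid")
}

#' Pearson correlation of a two-dimensional conditional density
#'
#' @param grid A 2-D [conditional_grid()].
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
conditional_correlation <- function(grid) {
  stopifnot(inherits(grid, "conditional_grid"), length(grid$dims) == 2L)
  w <- grid$density
  if (sum(w) <= 0) stop("conditional density has zero mass on the grid", call. = FALSE)
  a <- grid$axes[[1L]]; b <- grid$axes[[2L]]
  wa <- rowSums(w); wb <- colSums(w)
  ma <- sum(wa * a); mb <- sum(wb * b)
  va <- sum(wa * (a - ma)^2); vb <- sum(wb * (b - mb)^2)
  cab <- sum(w * outer(a - ma, b - mb))
  cab / sqrt(va * vb)
}

#' Average conditional correlation matrix
#'
#' Samples `n_conditions` conditioning points from the posterior, computes
#' the full pairwise conditional-correlation matrix at each (all other
#' parameters held at the conditioning point), and averages the matrices.
#'
#' @inheritParams conditional_grid
#' @param n_conditions Number of posterior-sampled conditioning points.
#' @param seed Integer seed for the conditioning draws.
#' @return List of class `conditional_corr` with `mean` (the averaged
#'   matrix, unit diagonal) and `per_condition` (array d x d x
#'   n_conditions).
#' @export
average_conditional_corr <- function(post, n_conditions = 50L,
                                     lower = NULL, upper = NULL,
                                     n_grid = 50L, seed = 1L) {
  stopifnot(n_conditions >= 1)
  pts <- geo_sample(post, n_conditions, seed = seed)
  d <- ncol(pts)
  arr <- array(NA_real_, c(d, d, n_conditions))
  for (c_i in seq_len(n_conditions)) {
    M <- diag(1, d)
    for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
      g <- conditional_grid(post, pts[c_i, ], c(i, j), lower, upper, n_grid)
      M[i, j] <- M[j, i] <- conditional_correlation(g)
    }
    arr[, , c_i] <- M
  }
  avg <- apply(arr, c(1, 2), mean)
  diag(avg) <- 1
  structure(list(mean = avg, per_condition = arr, n_conditions = n_conditions),
            class = "conditional_corr")
}

# ---- high-probability paths ---------------------------------------------

path_basis <- function(s, K) {
  # columns k = 1..K: sin(pi k s); columns K+1..2K: sin^2(pi k s)
  B <- matrix(0, length(s), 2L * K)
  for (k in seq_len(K)) B[, k] <- sin(pi * k * s)
  for (k in (K + 1L):(2L * K)) B[, k] <- sin(pi * k * s)^2
  B
}

#' Sinusoidal path parameterization between two parameter sets
#'
#' The curve
#' \deqn{\gamma(s) = \sum_k \alpha_{n,k} b_k(s) + (1-s)\theta_s + s\theta_g}
#' with basis functions `sin(pi k s)` (k = 1..K) and `sin^2(pi k s)`
#' (k = K+1..2K) vanishes at `s = 0, 1` for any coefficients, so the
#' endpoints are met exactly.
#'
#' @param theta_s,theta_g Endpoint parameter vectors.
#' @param K Basis functions per block (default 2, i.e. 2K coefficients per
#'   dimension).
#' @param n_points Discretization points for the path integral.
#' @param alpha Optional coefficient matrix (d x 2K), defaults to zero
#'   (the straight line).
#' @return Object of class `posterior_path`.
#' @export
path_parameterization <- function(theta_s, theta_g, K = 2L, n_points = 80L,
                                  alpha = NULL) {
  d <- length(theta_s)
  stopifnot(length(theta_g) == d, K >= 1, n_points >= 3)
  alpha <- alpha %||% matrix(0, d, 2L * K)
  stopifnot(nrow(alpha) == d, ncol(alpha) == 2L * K)
  structure(list(theta_s = as.numeric(theta_s), theta_g = as.numeric(theta_g),
                 K = as.integer(K), n_points = as.integer(n_points),
                 alpha = alpha),
            class = "posterior_path")
}

#' Evaluate a path at positions s between 0 and 1
#'
#' @param path A [path_parameterization()].
#' @param s Numeric vector of positions.
#' @return Matrix `length(s)` x d of parameter vectors.
#' @export
path_eval <- function(path, s) {
  B <- path_basis(s, path$K)
  dev <- B %*% t(path$alpha)
  line <- outer(1 - s, path$theta_s) + outer(s, path$theta_g)
  dev + line
}

# discretized path points, velocities (central differences) and
# trapezoid quadrature weights
path_discretize <- function(path) {
  n <- path$n_points
  s <- seq(0, 1, length.out = n)
  ds <- 1 / (n - 1)
  G <- path_eval(path, s)
  Gdot <- matrix(0, n, ncol(G))
  Gdot[2:(n - 1), ] <- (G[3:n, , drop = FALSE] - G[1:(n - 2), , drop = FALSE]) / (2 * ds)
  Gdot[1, ] <- (G[2, ] - G[1, ]) / ds
  Gdot[n, ] <- (G[n, ] - G[n - 1, ]) / ds
  w <- rep(ds, n); w[c(1, n)] <- ds / 2
  list(s = s, ds = ds, G = G, Gdot = Gdot, w = w)
}

#' Posterior-weighted path integral (the path loss)
#'
#' Discretization of
#' \deqn{L(\gamma) = \int_0^1 -\log p(\gamma(s) | x_o)\, \|\dot\gamma(s)\|\, ds}
#' over the path's `n_points` grid, with velocities from central finite
#' differences and trapezoid weights.  `-Inf` log-densities on the path
#' yield `+Inf` loss.
#'
#' @param path A [path_parameterization()].
#' @param post Posterior-like object.
#' @return Scalar loss.
#' @export
path_loss <- function(path, post) {
  pd <- path_discretize(path)
  lp <- geo_log_prob(post, pd$G)
  speed <- sqrt(rowSums(pd$Gdot^2))
  sum(-lp * speed * pd$w)
}

path_loss_grad <- function(path, post) {
  pd <- path_discretize(path)
  n <- path$n_points; d <- length(path$theta_s)
  lp <- geo_log_prob(post, pd$G)
  gl <- geo_grad(post, pd$G)               # n x d gradient of log p
  speed <- sqrt(rowSums(pd$Gdot^2))
  B <- path_basis(pd$s, path$K)            # n x 2K
  # dB/ds via the same finite-difference stencil used for Gdot
  Bdot <- matrix(0, n, ncol(B))
  Bdot[2:(n - 1), ] <- (B[3:n, , drop = FALSE] - B[1:(n - 2), , drop = FALSE]) / (2 * pd$ds)
  Bdot[1, ] <- (B[2, ] - B[1, ]) / pd$ds
  Bdot[n, ] <- (B[n, ] - B[n - 1, ]) / pd$ds
  sp_safe <- pmax(speed, 1e-12)
  # dL/dalpha_{n,k} = sum_i w_i [ -g_in B_ik speed_i + (-lp_i) (Gdot_in/speed_i) Bdot_ik ]
  t1 <- t(gl * (pd$w * speed)) %*% B                    # d x 2K
  t2 <- t(pd$Gdot / sp_safe * (pd$w * (-lp))) %*% Bdot  # d x 2K
  -t1 + t2
}

#' Minimize the path integral over the sinusoidal coefficients
#'
#' Gradient descent on the basis coefficients (endpoints are invariant by
#' construction).  Iterations that would make the loss non-finite are
#' rejected by halving the step; the best coefficients seen are returned.
#'
#' @param path Initial [path_parameterization()].
#' @param post Posterior-like object (a `grad` speeds this up; otherwise
#'   finite differences are used).
#' @param steps Gradient steps.
#' @param lr Learning rate.
#' @return Optimized `posterior_path` with attribute `loss_trace`.
#' @export
optimize_path <- function(path, post, steps = 2000L, lr = 1e-3) {
  best <- path
  best_loss <- path_loss(path, post)
  cur <- path
  cur_loss <- best_loss
  trace <- numeric(steps + 1L); trace[1L] <- best_loss
  step_lr <- lr
  for (it in seq_len(steps)) {
    g <- path_loss_grad(cur, post)
    cand <- cur
    cand$alpha <- cur$alpha - step_lr * g
    cl <- path_loss(cand, post)
    if (!is.finite(cl) || cl > cur_loss + abs(cur_loss)) {
      step_lr <- step_lr / 2
      if (step_lr < lr * 1e-6) break
      trace[it + 1L] <- cur_loss
      next
    }
    cur <- cand; cur_loss <- cl
    if (cl < best_loss) { best <- cand; best_loss <- cl }
    trace[it + 1L] <- cur_loss
  }
  attr(best, "loss_trace") <- trace[trace != 0 | seq_along(trace) == 1L]
  attr(best, "loss") <- best_loss
  best
}

# ---- orthogonal perturbations -------------------------------------------

#' Single gradient-projection step orthogonal to a path tangent
#'
#' Computes the constrained update
#' \deqn{\Delta\theta = -P \nabla \log p \,/\, (\nabla \log p)^T P \nabla\log p}
#' with the projector \eqn{P = I - n n^T / (n^T n)}: the direction of
#' steepest decrease of the posterior log-density within the hyperplane
#' orthogonal to the tangent `n`.
#'
#' @param post Posterior-like object.
#' @param theta Current parameter vector.
#' @param tangent Path tangent vector (nonzero).
#' @return The update vector; `attr(, "stop")` is `TRUE` when the
#'   projected gradient vanishes.
#' @export
orthogonal_step <- function(post, theta, tangent) {
  n <- as.numeric(tangent)
  if (sum(n^2) <= 0) stop("tangent must be nonzero", call. = FALSE)
  g <- as.numeric(geo_grad(post, theta))
  Pg <- g - n * (sum(n * g) / sum(n^2))
  denom <- sum(g * Pg)
  if (!is.finite(denom) || abs(denom) < 1e-300 || sum(Pg^2) < 1e-300) {
    out <- rep(0, length(n))
    attr(out, "stop") <- TRUE
    return(out)
  }
  out <- -Pg / denom
  attr(out, "stop") <- FALSE
  out
}

#' Orthogonal perturbation trajectory
#'
#' Iterates [orthogonal_step()] from a point on a high-probability path,
#' scaling each update to `step_size`, until the cumulative distance
#' traveled reaches `total_distance` (conventionally 1/27 of the
#' high-probability path length).
#'
#' @param post Posterior-like object.
#' @param theta0 Starting point.
#' @param tangent Path tangent at the starting point.
#' @param total_distance Distance at which to stop.
#' @param step_size Per-iteration step length.
#' @return A tibble with the trajectory: distance traveled and posterior
#'   log-density at each point.
#' @export
orthogonal_path <- function(post, theta0, tangent, total_distance,
                            step_size = total_distance / 50) {
  theta <- as.numeric(theta0)
  dist <- 0
  rows <- list(tibble::tibble(step = 0L, distance = 0,
                              log_prob = as.numeric(geo_log_prob(post, theta)),
                              theta = list(theta)))
  it <- 0L
  while (dist < total_distance) {
    it <- it + 1L
    dth <- orthogonal_step(post, theta, tangent)
    if (isTRUE(attr(dth, "stop"))) break
    dth <- dth / sqrt(sum(dth^2)) * step_size
    theta <- theta + dth
    dist <- dist + step_size
    rows[[it + 1L]] <- tibble::tibble(step = it, distance = dist,
                                      log_prob = as.numeric(geo_log_prob(post, theta)),
                                      theta = list(theta))
    if (it > 10000L) break
  }
  dplyr::bind_rows(rows)
}
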