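# Baseline likelihood-free inference methods (rejection ABC, SMC-ABC),
# a generic adaptive-Metropolis MCMC reference for tractable models, the
# relative Kullback-Leibler error metric, the per-feature objective score
# used by the genetic-algorithm comparison, and posterior-predictive
# checks.

scaled_distance <- function(X, x_o, scale = NULL) {
  X <- as_row_matrix(X)
  scale <- scale %||% rep(1, length(x_o))
  D <- sweep(X, 2L, as.numeric(x_o), "-")
  D <- sweep(D, 2L, scale, "/")
  sqrt(rowSums(D^2))
}

#' Rejection ABC
#'
#' Draws `budget` parameters from the prior, simulates, and accepts those
#' whose scaled Euclidean feature distance to the observation falls below
#' `epsilon` (or below the `accept_quantile` distance quantile when
#' `epsilon` is `NULL`).
#'
#' @param simulator,extractor,prior,x_o As in [run_snpe()].
#' @param budget Number of prior simulations.
#' @param epsilon Acceptance tolerance (absolute distance), or `NULL`.
#' @param accept_quantile Acceptance quantile used when `epsilon` is
#'   `NULL` (default 0.01).
#' @param scale Per-feature distance scale factors.
#' @param seed Integer seed.
#' @return A tibble of accepted parameters with their distances; the full
#'   simulation table is attached as `attr(, "table")`.
#' @export
rejection_abc <- function(simulator, extractor, prior, x_o, budget = 1000L,
                          epsilon = NULL, accept_quantile = 0.01,
                          scale = NULL, seed = 1L) {
  tab <- run_simulations(prior, simulator, extractor, budget, seed = seed)
  tm <- table_matrices(tab)
  d <- rep(Inf, nrow(tab))
  d[tm$valid] <- scaled_distance(tm$x[tm$valid, , drop = FALSE], x_o, scale)
  eps <- epsilon %||% as.numeric(quantile(d[is.finite(d)], accept_quantile))
  keep <- which(d <= eps)
  if (length(keep) == 0L) {
    warning("rejection ABC accepted no samples at the given tolerance", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(tm$theta[keep, , drop = FALSE]))
  out$distance <- d[keep]
  attr(out, "epsilon") <- eps
  attr(out, "table") <- tab
  out
}

#' Sequential Monte Carlo ABC
#'
#' Population Monte Carlo scheme: an initial prior population is refined
#' over generations with a Gaussian perturbation kernel of twice the
#' weighted empirical population covariance; each generation's tolerance
#' is the `accept_quantile` quantile of the previous accepted distances,
#' so tolerances are non-increasing.  Stops when the simulation budget is
#' exhausted or the effective sample size collapses.
#'
#' @inheritParams rejection_abc
#' @param n_particles Population size.
#' @param budget Total simulation budget across generations.
#' @param accept_quantile Tolerance-shrink quantile (default 0.5).
#' @param min_ess Early-stop threshold on effective sample size.
#' @return List with `particles` (matrix), normalized `weights`,
#'   `epsilons`, `n_sims` used, and `generations` completed.
#' @export
smc_abc <- function(simulator, extractor, prior, x_o, n_particles = 200L,
                    budget = 5000L, accept_quantile = 0.5, scale = NULL,
                    min_ess = 10, seed = 1L) {
  stopifnot(budget >= n_particles)
  set.seed(child_seed(seed, 0L))
  d_par <- prior_dim(prior)
  # generation 1 = rejection ABC: keep the n_particles closest prior draws
  n1 <- min(budget, ceiling(n_particles / accept_quantile))
  tab <- run_simulations(prior, simulator, extractor, n1,
                         seed = child_seed(seed, 1L))
  tm <- table_matrices(tab)
  dist0 <- rep(Inf, n1)
  dist0[tm$valid] <- scaled_distance(tm$x[tm$valid, , drop = FALSE], x_o, scale)
  ord <- order(dist0)[seq_len(min(n_particles, sum(is.finite(dist0))))]
  particles <- tm$theta[ord, , drop = FALSE]
  dist <- dist0[ord]
  n_particles <- nrow(particles)
  weights <- rep(1 / n_particles, n_particles)
  n_sims <- n1
  eps <- max(dist)
  epsilons <- eps
  gen <- 1L
  sim_counter <- 1000L
  while (n_sims < budget) {
    eps <- min(eps, as.numeric(quantile(dist, accept_quantile)))
    wcov <- stats::cov.wt(particles, wt = weights, method = "ML")$cov
    pert <- 2 * wcov + diag(1e-10, d_par)
    ch <- chol(pert)
    new_p <- matrix(NA_real_, 0L, d_par)
    new_d <- numeric(0)
    while (nrow(new_p) < n_particles && n_sims < budget) {
      j <- sample.int(n_particles, 1L, prob = weights)
      cand <- particles[j, ] + as.numeric(rnorm(d_par) %*% ch)
      if (!all(is.finite(prior_log_density(prior, cand)))) next
      sim_counter <- sim_counter + 1L
      xi <- tryCatch(as.numeric(extractor(
        simulator(cand, child_seed(seed, sim_counter)))),
        error = function(e) NULL)
      n_sims <- n_sims + 1L
      if (is.null(xi) || !all(is.finite(xi))) next
      di <- scaled_distance(matrix(xi, 1L), x_o, scale)
      if (di < eps) {
        new_p <- rbind(new_p, cand)
        new_d <- c(new_d, di)
      }
    }
    if (nrow(new_p) < 2L) break
    # importance reweighting against the perturbation mixture
    new_w <- vapply(seq_len(nrow(new_p)), function(i) {
      dev <- sweep(particles, 2L, new_p[i, ], "-")
      y <- t(backsolve(ch, t(dev), transpose = TRUE))
      kern <- exp(-0.5 * rowSums(y^2))
      pl <- prior_log_density(prior, new_p[i, ])
      exp(pl) / sum(weights * kern)
    }, numeric(1))
    if (!any(new_w > 0)) break
    new_w <- new_w / sum(new_w)
    ess <- 1 / sum(new_w^2)
    np <- nrow(new_p)
    if (np < n_particles) {
      # budget ran out mid-generation; keep the partial population
      particles <- new_p; weights <- new_w
      dist <- new_d
      gen <- gen + 1L
      epsilons <- c(epsilons, eps)
      if (ess < min_ess) warning("SMC-ABC population collapse (low ESS)", call. = FALSE)
      break
    }
    particles <- new_p; weights <- new_w; dist <- new_d
    gen <- gen + 1L
    eps <- as.numeric(quantile(dist, accept_quantile))
    epsilons <- c(epsilons, eps)
    if (ess < min_ess) {
      warning("SMC-ABC population collapse (low ESS)", call. = FALSE)
      break
    }
  }
  list(particles = particles, weights = weights / sum(weights),
       distances = dist, epsilons = epsilons, n_sims = n_sims,
       generations = gen)
}

#' Adaptive random-walk Metropolis reference sampler
#'
#' Generic MCMC for models with tractable (unnormalized) log-posteriors,
#' used to produce reference posteriors on the encoding-model toys.
#' Proposal covariance adapts toward `2.38^2/d` times the empirical
#' covariance of the chain so far.
#'
#' @param log_post `function(theta)` returning the unnormalized
#'   log-posterior of one parameter vector.
#' @param init Initial parameter vector (finite log-posterior required).
#' @param n_samples Number of retained samples (after burn-in, before
#'   thinning).
#' @param burn Burn-in iterations (default `n_samples / 2`).
#' @param thin Thinning factor.
#' @param init_scale Initial isotropic proposal SD.
#' @param adapt Adapt the proposal covariance during burn-in.
#' @param seed Integer seed.
#' @return List with `samples` (matrix), `acceptance` rate, and
#'   `diagnostics` (flags degenerate mixing).
#' @export
mcmc_reference <- function(log_post, init, n_samples = 5000L, burn = NULL,
                           thin = 1L, init_scale = 0.1, adapt = TRUE,
                           seed = 1L) {
  set.seed(as.integer(seed))
  d <- length(init)
  burn <- burn %||% max(500L, n_samples %/% 2L)
  lp0 <- log_post(init)
  if (!is.finite(lp0)) stop("log-posterior not finite at init", call. = FALSE)
  n_iter <- burn + n_samples * thin
  chain <- matrix(NA_real_, n_iter, d)
  cur <- as.numeric(init); cur_lp <- lp0
  C <- diag(init_scale^2, d)
  ch <- chol(C)
  acc <- 0L
  acc_win <- 0L
  for (t in seq_len(n_iter)) {
    cand <- cur + as.numeric(rnorm(d) %*% ch)
    lp <- log_post(cand)
    if (is.finite(lp) && log(runif(1)) < lp - cur_lp) {
      cur <- cand; cur_lp <- lp; acc <- acc + 1L; acc_win <- acc_win + 1L
    }
    chain[t, ] <- cur
    if (t == 1000L && acc == 0L) {
      stop("MCMC: zero acceptance over 1000 proposals", call. = FALSE)
    }
    if (adapt && t <= burn && t %% 200L == 0L && t >= 400L) {
      emp <- cov(chain[seq_len(t), , drop = FALSE])
      C <- 2.38^2 / d * emp + diag(1e-8, d)
      ch <- tryCatch(chol(C), error = function(e) ch)
    }
  }
  keep <- chain[burn + seq(1L, n_samples * thin, by = thin), , drop = FALSE]
  step_sizes <- sqrt(rowSums(diff(keep)^2))
  # a well-tuned random-walk chain accepts a fraction well below one;
  # near-certain acceptance means the proposal barely moves
  sticky <- acc / n_iter > 0.95
  if (sticky) warning("MCMC diagnostic: near-certain acceptance, negligible moves", call. = FALSE)
  list(samples = keep, acceptance = acc / n_iter,
       diagnostics = list(sticky = sticky, mean_step = mean(step_sizes)))
}

#' Relative error in Kullback-Leibler divergence
#'
#' Monte-Carlo estimate of
#' \deqn{D_{KL}(p_{ref} \| \hat p) / D_{KL}(p_{ref} \| p_{prior})}
#' over samples from the reference posterior: 0 means perfect recovery of
#' the reference posterior, 1 means the estimate is no better than the
#' prior.
#'
#' @param ref_samples Matrix of reference-posterior samples.
#' @param ref_log_density `function(theta)` normalized reference
#'   log-density.
#' @param candidate_log_density `function(theta)` normalized candidate
#'   log-density.
#' @param prior_log_density_fn `function(theta)` normalized prior
#'   log-density.
#' @return A list of class `kl_estimate` with `value`, Monte-Carlo `se`,
#'   and the two divergence estimates.
#' @export
relative_kl <- function(ref_samples, ref_log_density, candidate_log_density,
                        prior_log_density_fn) {
  ref_samples <- as_row_matrix(ref_samples)
  lr <- ref_log_density(ref_samples)
  lc <- candidate_log_density(ref_samples)
  lp <- prior_log_density_fn(ref_samples)
  a <- lr - lc      # per-sample numerator terms
  b <- lr - lp
  num <- mean(a); den <- mean(b)
  if (!is.finite(den) || den <= 0) {
    stop("relative KL undefined: nonpositive prior divergence estimate", call. = FALSE)
  }
  n <- length(a)
  ratio <- num / den
  # delta-method Monte-Carlo standard error of the ratio
  se <- sqrt(max(0, var(a) / num^2 + var(b) / den^2 -
                   2 * cov(a, b) / (num * den)) / n) * abs(ratio)
  structure(list(value = ratio, se = se, d_candidate = num, d_prior = den,
                 n = n), class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("relative KL error: %.4f (MC se %.4f, n = %d)\n",
              x$value, x$se, x$n))
  invisible(x)
}

#' Per-feature objective score used by the genetic-algorithm comparison
#'
#' \eqn{\epsilon_{ij} = |x_{ij} - x_{oj}| / \sigma_j} per feature, plus
#' their sum: the score minimized by the evolutionary optimizer's
#' hall-of-fame.
#'
#' @param x_sim Simulated feature vector or matrix (rows = simulations).
#' @param x_o Observed feature vector.
#' @param sigma Per-feature standard deviations (positive).
#' @return A tibble with one row per simulation: per-feature scores and
#'   `total`.
#' @export
ibea_objective <- function(x_sim, x_o, sigma) {
  x_sim <- as_row_matrix(x_sim)
  stopifnot(length(x_o) == ncol(x_sim), length(sigma) == ncol(x_sim))
  if (any(sigma <= 0)) stop("feature standard deviations must be positive", call. = FALSE)
  S <- abs(sweep(x_sim, 2L, as.numeric(x_o), "-"))
  S <- sweep(S, 2L, as.numeric(sigma), "/")
  out <- tibble::as_tibble(as.data.frame(S))
  names(out) <- paste0("eps_", seq_len(ncol(S)))
  out$total <- rowSums(S)
  out
}

#' Posterior predictive check
#'
#' Simulates from `n` posterior draws and summarizes each feature of the
#' predictive distribution (mean, SD) together with the rank of the
#' observed feature among the predictive samples.
#'
#' @param post An `snpe_posterior` (or any object accepted by
#'   [posterior_sample()]).
#' @param simulator,extractor As in [run_simulations()].
#' @param x_o Observed feature vector.
#' @param n Number of posterior draws (>= 10).
#' @param seed Integer seed.
#' @return A tibble with one row per feature: predictive mean, sd, the
#'   rank statistic of `x_o` (fraction of predictive draws below it), and
#'   whether `x_o` falls inside the central 99% predictive interval.
#' @export
posterior_predictive_check <- function(post, simulator, extractor, x_o,
                                       n = 100L, seed = 1L) {
  stopifnot(n >= 10)
  tab <- run_simulations(post, simulator, extractor, n, seed = seed)
  tm <- table_matrices(tab)
  if (!any(tm$valid)) stop("all posterior-predictive draws invalid", call. = FALSE)
  X <- tm$x[tm$valid, , drop = FALSE]
  x_o <- as.numeric(x_o)
  tibble::tibble(
    feature = seq_along(x_o),
    observed = x_o,
    pred_mean = colMeans(X),
    pred_sd = apply(X, 2L, sd),
    rank = vapply(seq_along(x_o),
                  function(j) mean(X[, j] < x_o[j]) + 0.5 * mean(X[, j] == x_o[j]),
                  numeric(1)),
    in_central99 = vapply(seq_along(x_o), function(j) {
      q <- quantile(X[, j], c(0.005, 0.995))
      x_o[j] >= q[1] && x_o[j] <= q[2]
    }, logical(1))
  )
}
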