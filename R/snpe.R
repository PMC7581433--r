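# The SNPE loop: draw parameters from a proposal, simulate, extract
# summary features, train the conditional density estimator on all pooled
# rounds (with SNPE-B importance weights when the proposal is not the
# prior), and expose the trained network conditioned on the observation as
# a posterior object truncated to the prior support.

# ---- simulation tables --------------------------------------------------

#' Assemble a simulation table
#'
#' A simulation table is a tibble with one row per simulation: parameter
#' columns `theta_*`, feature columns `x_*`, the round index, a validity
#' flag, the per-row simulation seed and the SNPE-B importance weight.
#' Rows whose simulation failed or produced non-finite features keep their
#' parameters but carry `NA` features and `valid = FALSE`.
#'
#' @param theta Parameter matrix.
#' @param x Feature matrix (`NA` rows allowed).
#' @param round Round index (scalar or per-row).
#' @param valid Logical validity flags.
#' @param seed Per-row integer seeds.
#' @param weight Per-row importance weights.
#' @return A tibble of class `simulation_table`.
#' @export
simulation_table <- function(theta, x, round = 1L, valid = TRUE,
                             seed = NA_integer_, weight = 1) {
  theta <- as_row_matrix(theta)
  x <- as_row_matrix(x)
  n <- nrow(theta)
  colnames(theta) <- paste0("theta_", seq_len(ncol(theta)))
  colnames(x) <- paste0("x_", seq_len(ncol(x)))
  out <- tibble::as_tibble(as.data.frame(theta))
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(x)))
  out$round <- rep_len(as.integer(round), n)
  out$valid <- rep_len(valid, n)
  out$seed <- rep_len(as.integer(seed), n)
  out$weight <- rep_len(weight, n)
  class(out) <- c("simulation_table", class(out))
  out
}

# Extract theta / x matrices and flags from a simulation table.
table_matrices <- function(tab) {
  tcols <- grep("^theta_", names(tab), value = TRUE)
  xcols <- grep("^x_", names(tab), value = TRUE)
  list(theta = as.matrix(tab[, tcols, drop = FALSE]),
       x = as.matrix(tab[, xcols, drop = FALSE]),
       valid = tab$valid,
       weight = tab$weight,
       round = tab$round)
}

# ---- proposals ----------------------------------------------------------

# A proposal is a prior, an snpe_posterior, or a list with $sample(n) and
# $log_density(theta) functions.
proposal_sample <- function(proposal, n) {
  if (inherits(proposal, "prior")) {
    prior_sample(proposal, n)
  } else if (inherits(proposal, "snpe_posterior")) {
    posterior_sample(proposal, n)
  } else if (is.list(proposal) && is.function(proposal$sample)) {
    proposal$sample(n)
  } else {
    stop("unsupported proposal object", call. = FALSE)
  }
}

proposal_log_density <- function(proposal, theta) {
  if (inherits(proposal, "prior")) {
    prior_log_density(proposal, theta)
  } else if (inherits(proposal, "snpe_posterior")) {
    posterior_log_prob(proposal, theta) - log(proposal$support_mass)
  } else if (is.list(proposal) && is.function(proposal$log_density)) {
    proposal$log_density(theta)
  } else {
    stop("unsupported proposal object", call. = FALSE)
  }
}

# ---- simulation ---------------------------------------------------------

#' Run simulations at proposal-sampled parameters
#'
#' Draws `n` parameter vectors from the proposal, runs the simulator at
#' each (with a per-row seed derived from `seed`), and reduces raw output
#' to summary features.  Simulator errors and non-finite feature vectors
#' mark the row invalid rather than dropping it, so the simulation budget
#' is always accounted for.
#'
#' @param proposal A `prior`, `snpe_posterior`, or list with `sample` /
#'   `log_density` functions.
#' @param simulator `function(theta, seed)` returning raw model output for
#'   one parameter vector.
#' @param extractor `function(raw)` returning a numeric feature vector.
#' @param n Number of simulations.
#' @param seed Integer seed; row `i` uses `child_seed(seed, i)`.
#' @param round Round index stored in the table.
#' @return A [simulation_table()] with exactly `n` rows.
#' @export
run_simulations <- function(proposal, simulator, extractor, n, seed = 1L,
                            round = 1L) {
  stopifnot(n >= 1)
  set.seed(child_seed(seed, 0L))
  theta <- proposal_sample(proposal, n)
  seeds <- vapply(seq_len(n), function(i) child_seed(seed, i), integer(1))
  feats <- vector("list", n)
  valid <- logical(n)
  n_feat <- NA_integer_
  for (i in seq_len(n)) {
    xi <- tryCatch({
      raw <- simulator(theta[i, ], seeds[i])
      as.numeric(extractor(raw))
    }, error = function(e) NULL)
    if (!is.null(xi) && length(xi) > 0L && all(is.finite(xi))) {
      feats[[i]] <- xi
      valid[i] <- TRUE
      if (is.na(n_feat)) n_feat <- length(xi)
    }
  }
  if (is.na(n_feat)) {
    warning("all simulations failed feature extraction", call. = FALSE)
    n_feat <- 1L
  }
  X <- matrix(NA_real_, n, n_feat)
  for (i in which(valid)) X[i, ] <- feats[[i]]
  simulation_table(theta, X, round = round, valid = valid, seed = seeds)
}

#' SNPE-B importance weights
#'
#' Ratio of prior to proposal density, \eqn{w_j = p(\theta_j)/\tilde
#' p(\theta_j)}: rows drawn from a focused proposal are down-weighted where
#' the proposal over-represents them, so the weighted log-density loss
#' still targets the true posterior.  Weights are zero outside the prior
#' support.
#'
#' @param thetas Parameter matrix.
#' @param prior A `prior` object.
#' @param proposal The proposal the parameters were drawn from.
#' @return Nonnegative weight vector.
#' @export
importance_weights <- function(thetas, prior, proposal) {
  thetas <- as_row_matrix(thetas)
  lp <- prior_log_density(prior, thetas)
  lq <- proposal_log_density(proposal, thetas)
  w <- numeric(nrow(thetas))
  inside <- is.finite(lp)
  if (any(inside & !is.finite(lq))) {
    stop("proposal density is zero at a sampled parameter (inconsistent proposal)",
         call. = FALSE)
  }
  w[inside] <- exp(lp[inside] - lq[inside])
  w
}

# ---- the SNPE loop ------------------------------------------------------

#' Sequential neural posterior estimation
#'
#' Runs `rounds` rounds of simulation and density-estimator training.  The
#' first round draws parameters from the prior; later rounds draw from the
#' current posterior estimate at the observation, truncated to the prior
#' support (SNPE-B: pooled training rows carry importance weights
#' prior/proposal).  With `rounds = 1` the trained network is amortized:
#' it performs inference for any observation covered by the prior.
#'
#' @param prior A `prior` object.
#' @param simulator,extractor As in [run_simulations()].
#' @param x_o Observed feature vector.
#' @param config Estimator configuration ([mdn_config()] or
#'   [maf_config()]).  If `NULL`, a two-layer MDN is configured
#'   automatically.
#' @param rounds Number of rounds (>= 1).
#' @param n_per_round Simulations per round (scalar or vector of length
#'   `rounds`).
#' @param seed Integer master seed.
#' @param weight_clip Optional upper bound on importance weights (off by
#'   default; narrow proposals can otherwise produce high-variance
#'   weights).
#' @param verbose Print round-level progress.
#' @return An object of class `snpe_posterior`.
#' @export
run_snpe <- function(prior, simulator, extractor, x_o, config = NULL,
                     rounds = 1L, n_per_round = 1000L, seed = 1L,
                     weight_clip = NULL, verbose = FALSE) {
  stopifnot(rounds >= 1, all(n_per_round >= 1))
  n_per_round <- rep_len(n_per_round, rounds)
  x_o <- as.numeric(x_o)
  tabs <- list()
  est <- NULL
  proposal <- prior
  for (r in seq_len(rounds)) {
    if (verbose) message(sprintf("round %d: simulating %d", r, n_per_round[r]))
    tab <- run_simulations(proposal, simulator, extractor, n_per_round[r],
                           seed = child_seed(seed, 100L + r), round = r)
    if (!any(tab$valid)) {
      if (r == 1L && rounds == 1L) stop("no valid simulations in round 1", call. = FALSE)
    }
    tm <- table_matrices(tab)
    w <- if (r == 1L) rep(1, nrow(tab)) else importance_weights(tm$theta, prior, proposal)
    if (!is.null(weight_clip)) w <- pmin(w, weight_clip)
    tab$weight <- w
    tabs[[r]] <- tab
    pooled <- dplyr::bind_rows(tabs)
    pm <- table_matrices(pooled)
    keep <- pm$valid
    if (!any(keep)) stop("no valid simulations in any round", call. = FALSE)
    if (is.null(config)) {
      config <- mdn_config(n_params = ncol(pm$theta), n_features = ncol(pm$x))
    }
    if (verbose) message(sprintf("round %d: training on %d valid rows", r, sum(keep)))
    est <- train_estimator(pm$theta[keep, , drop = FALSE], config,
                           weights = pm$weight[keep],
                           x = pm$x[keep, , drop = FALSE],
                           seed = child_seed(seed, 200L + r),
                           init = est)   # warm start across rounds
    post <- new_snpe_posterior(est, x_o, prior, r, pooled)
    proposal <- post
  }
  post
}

new_snpe_posterior <- function(est, x_o, prior, rounds, table = NULL) {
  post <- structure(list(
    estimator = est, x_o = as.numeric(x_o), prior = prior,
    rounds = rounds, table = table, support_mass = 1
  ), class = "snpe_posterior")
  # estimate the prior-support mass of the raw estimator (used to
  # normalize the truncated density when the posterior serves as proposal)
  z <- tryCatch({
    th <- estimator_sample(est, x_o, 2000L, seed = 997L)
    max(mean(prior_in_support(prior, th)), 1e-4)
  }, error = function(e) 1)
  post$support_mass <- z
  post
}

#' Posterior log-density (prior-support truncated)
#'
#' Delegates to the trained estimator's conditional log-density at the
#' bound observation; parameters outside the prior support get `-Inf`.
#'
#' @param post An `snpe_posterior`.
#' @param theta Parameter vector or matrix of row vectors.
#' @return Numeric vector of log-densities.
#' @export
posterior_log_prob <- function(post, theta) {
  theta <- as_row_matrix(theta)
  lp <- rep(-Inf, nrow(theta))
  inside <- prior_in_support(post$prior, theta)
  if (any(inside)) {
    lp[inside] <- estimator_log_prob(post$estimator,
                                     theta[inside, , drop = FALSE], post$x_o)
  }
  lp
}

#' Gradient of the posterior log-density
#'
#' Analytic for MDN-based posteriors (inside the support); finite
#' differences otherwise.
#'
#' @inheritParams posterior_log_prob
#' @return Gradient matrix, one row per parameter vector.
#' @export
posterior_log_prob_grad <- function(post, theta) {
  estimator_log_prob_grad(post$estimator, theta, post$x_o)
}

#' Sample from an SNPE posterior
#'
#' Rejection-samples the trained conditional density against the prior
#' support: draws are resampled until inside, with a cap of `max_tries`
#' proposal draws per requested sample.
#'
#' @param post An `snpe_posterior`.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param max_tries Cap on total proposal draws, as a multiple of `n`.
#' @return An `n` x `d` matrix of parameter samples inside the support.
#' @export
posterior_sample <- function(post, n, seed = NULL, max_tries = 1e4) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- prior_dim(post$prior)
  out <- matrix(NA_real_, 0L, d)
  tried <- 0L; accepted <- 0L
  while (nrow(out) < n && tried < max_tries * n) {
    m <- min(max(2L * (n - nrow(out)), 100L), 10 * n)
    th <- estimator_sample(post$estimator, post$x_o, m)
    tried <- tried + m
    keep <- prior_in_support(post$prior, th)
    accepted <- accepted + sum(keep)
    out <- rbind(out, th[keep, , drop = FALSE])
  }
  if (nrow(out) < n) {
    stop("posterior sampling: support rejection cap exceeded", call. = FALSE)
  }
  out <- out[seq_len(n), , drop = FALSE]
  attr(out, "acceptance_rate") <- accepted / tried
  out
}

#' @export
print.snpe_posterior <- function(x, ...) {
  cat(sprintf("<snpe_posterior> %d parameters, %d round(s), %s estimator\n",
              prior_dim(x$prior), x$rounds,
              if (inherits(x$estimator, "mdn_estimator")) "MDN" else "MAF"))
  invisible(x)
}
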