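# ABC baselines, the MCMC reference sampler, the relative-KL metric, the
# per-feature objective score, and posterior-predictive checks.

toy_1d <- function() {
  list(prior = prior_gaussian(0, matrix(1)),
       simulator = function(th, seed) { set.seed(seed); th + rnorm(1) },
       extractor = identity)
}

test_that("rejection ABC approaches the conjugate posterior as eps shrinks", {
  toy <- toy_1d()
  acc <- rejection_abc(toy$simulator, toy$extractor, toy$prior, x_o = 0,
                       budget = 40000, accept_quantile = 0.01, seed = 2)
  expect_equal(var(acc$theta_1), 0.5, tolerance = 0.05)
  expect_equal(mean(acc$theta_1), 0, tolerance = 0.1)

  # infinite tolerance returns the prior
  acc2 <- rejection_abc(toy$simulator, toy$extractor, toy$prior, x_o = 0,
                        budget = 10000, epsilon = Inf, seed = 3)
  ks <- suppressWarnings(ks.test(acc2$theta_1, "pnorm"))
  expect_lt(unname(ks$statistic), 0.03)

  # deterministic simulator: acceptance is a hard distance cut
  det <- rejection_abc(function(th, seed) th, identity,
                       prior_box(-2, 2), x_o = 0.5,
                       budget = 2000, epsilon = 0.1, seed = 4)
  expect_true(all(abs(det$theta_1 - 0.5) <= 0.1))
})

test_that("SMC-ABC refines toward the conjugate posterior", {
  toy <- toy_1d()
  sm <- smc_abc(toy$simulator, toy$extractor, toy$prior, x_o = 0,
                n_particles = 400, budget = 8000, seed = 5)
  expect_equal(sum(sm$weights), 1, tolerance = 1e-12)
  expect_true(all(diff(sm$epsilons) <= 1e-12))
  wm <- sum(sm$weights * sm$particles[, 1])
  wv <- sum(sm$weights * (sm$particles[, 1] - wm)^2)
  expect_equal(wv, 0.5, tolerance = 0.1)

  # a budget that only covers the first generation reduces to rejection
  # ABC: the particles are exactly the n closest of the initial draws
  n1 <- ceiling(200 / 0.5)
  sm1 <- smc_abc(toy$simulator, toy$extractor, toy$prior, x_o = 0,
                 n_particles = 200, budget = n1, seed = 6)
  expect_equal(sm1$generations, 1L)
  tab <- run_simulations(toy$prior, toy$simulator, toy$extractor, n1,
                         seed = child_seed(6, 1L))
  d <- abs(snpet:::table_matrices(tab)$x[, 1] - 0)
  expect_setequal(round(sm1$particles[, 1], 12),
                  round(snpet:::table_matrices(tab)$theta[order(d)[1:200], 1], 12))
})

test_that("relative KL matches closed-form Gaussian divergences", {
  ref <- analytic_posterior(0, matrix(1))
  set.seed(9)
  rs <- ref$sample(4000)
  cand <- analytic_posterior(1, matrix(1))
  prior <- analytic_posterior(0, matrix(100))
  # identical densities: 0; the prior itself: 1
  expect_equal(relative_kl(rs, ref$log_prob, ref$log_prob, prior$log_prob)$value,
               0, tolerance = 1e-12)
  expect_equal(relative_kl(rs, ref$log_prob, prior$log_prob, prior$log_prob)$value,
               1, tolerance = 1e-12)
  est <- relative_kl(rs, ref$log_prob, cand$log_prob, prior$log_prob)
  exact <- 0.5 / (log(10) - 0.5 * (1 - 1 / 100))
  expect_lt(abs(est$value - exact), 0.02)
  expect_lt(est$se, 0.02)
  expect_error(relative_kl(rs, ref$log_prob, cand$log_prob, ref$log_prob),
               "nonpositive")
})

test_that("the per-feature objective score is a scaled absolute error", {
  x_o <- c(1, 2, 3)
  sig <- c(0.5, 1, 2)
  s0 <- ibea_objective(x_o, x_o, sig)
  expect_equal(as.numeric(s0[1, 1:3]), rep(0, 3))
  expect_equal(s0$total, 0)
  s1 <- ibea_objective(x_o + c(0.5, 0, 0), x_o, sig)
  expect_equal(s1$eps_1, 1)
  expect_equal(s1$total, 1)
  # joint rescaling invariance
  s2 <- ibea_objective(7 * (x_o + c(0.5, 0, 0)), 7 * x_o, 7 * sig)
  expect_equal(as.data.frame(s2), as.data.frame(s1), tolerance = 1e-12)
  expect_error(ibea_objective(x_o, x_o, c(1, 0, 1)), "positive")
})

test_that("the adaptive Metropolis reference samples a known target", {
  mc <- mcmc_reference(function(th) -0.5 * sum(th^2), init = 0.5,
                       n_samples = 1e5, burn = 5000, seed = 11)
  expect_equal(mean(mc$samples), 0, tolerance = 0.05)
  expect_equal(var(as.numeric(mc$samples)), 1, tolerance = 0.1)
  expect_gt(mc$acceptance, 0.1)

  # reproducibility
  m1 <- mcmc_reference(function(th) -0.5 * sum(th^2), 0, 500, burn = 1000,
                       init_scale = 1, seed = 3)
  m2 <- mcmc_reference(function(th) -0.5 * sum(th^2), 0, 500, burn = 1000,
                       init_scale = 1, seed = 3)
  expect_identical(m1$samples, m2$samples)

  # a vanishing proposal accepts everything but goes nowhere
  expect_warning(
    mcmc_reference(function(th) -0.5 * sum(th^2), 0, 2000, burn = 500,
                   init_scale = 1e-9, adapt = FALSE, seed = 7),
    "negligible")
})

test_that("posterior predictive checks are calibrated on the conjugate toy", {
  cp <- conjugate_posterior_fixture()
  fx <- cp$fx
  ppc <- posterior_predictive_check(cp$post, fx$simulator, fx$extractor,
                                    x_o = c(0, 0), n = 200, seed = 13)
  expect_true(all(ppc$in_central99))
  expect_true(all(ppc$rank > 0.01 & ppc$rank < 0.99))

  # a point-mass posterior with a deterministic simulator is an exact match
  pm <- list(sample = function(n) matrix(rep(c(0.3, -0.2), each = n), n))
  ppc2 <- posterior_predictive_check(pm, function(th, seed) th, identity,
                                     x_o = c(0.3, -0.2), n = 50, seed = 1)
  expect_equal(ppc2$pred_sd, c(0, 0), ignore_attr = TRUE)
  expect_equal(ppc2$pred_mean, ppc2$observed, ignore_attr = TRUE)

  # rank statistics of a held-out data replicate over repeated synthetic
  # observations are uniform (in-sample ranks are conservative by the
  # usual posterior-predictive-p-value argument)
  an_prior <- fx$prior
  ranks <- matrix(NA_real_, 100, 2)
  for (r in 1:100) {
    th_star <- prior_sample(an_prior, 1, seed = 500 + r)[1, ]
    x_star <- fx$simulator(th_star, seed = 900 + r)
    x_rep <- fx$simulator(th_star, seed = 1900 + r)
    an <- fx$posterior(x_star)
    pp <- posterior_predictive_check(list(sample = an$sample),
                                     fx$simulator, fx$extractor,
                                     x_o = x_rep, n = 60, seed = 700 + r)
    ranks[r, ] <- pp$rank
  }
  for (j in 1:2) {
    b <- table(cut(ranks[, j], breaks = seq(0, 1, by = 0.2)))
    cs <- sum((b - 20)^2 / 20)
    expect_gt(pchisq(cs, df = 4, lower.tail = FALSE), 0.01)
  }
})
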