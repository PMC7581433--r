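# The SNPE loop: simulation tables, importance weights, posterior
# objects, amortization and multi-round behavior.

test_that("run_simulations records parameters, features and flags", {
  prior <- prior_box(c(-1, -1), c(1, 1))
  tab <- run_simulations(prior, function(th, seed) th, identity, 3, seed = 1)
  tm <- snpet:::table_matrices(tab)
  expect_equal(nrow(tab), 3L)
  expect_equal(tm$x, unname(tm$theta), ignore_attr = TRUE)
  expect_true(all(tab$valid))
  expect_equal(tab$round, rep(1L, 3))

  # determinism under a fixed seed
  tab2 <- run_simulations(prior, function(th, seed) {
    set.seed(seed); th + rnorm(2)
  }, identity, 5, seed = 9)
  tab3 <- run_simulations(prior, function(th, seed) {
    set.seed(seed); th + rnorm(2)
  }, identity, 5, seed = 9)
  expect_identical(as.data.frame(tab2), as.data.frame(tab3))
})

test_that("failing simulations are flagged invalid, not dropped", {
  prior <- prior_box(c(-1), c(1))
  sim <- function(th, seed) if (th[1] < 0) stop("boom") else th
  tab <- run_simulations(prior, sim, identity, 50, seed = 3)
  expect_equal(nrow(tab), 50L)
  tm <- snpet:::table_matrices(tab)
  expect_equal(tab$valid, tm$theta[, 1] >= 0, ignore_attr = TRUE)
  expect_true(all(is.na(tm$x[!tab$valid, 1])))

  # all-failing simulator warns and returns an all-invalid table
  expect_warning(
    tab_bad <- run_simulations(prior, function(th, seed) stop("no"),
                               identity, 5, seed = 1),
    "failed")
  expect_false(any(tab_bad$valid))

  # non-finite features also invalidate the row
  sim2 <- function(th, seed) if (th[1] > 0) c(th, NaN) else c(th, 1)
  tab4 <- run_simulations(prior, sim2, identity, 40, seed = 5)
  expect_equal(tab4$valid, snpet:::table_matrices(tab4)$theta[, 1] <= 0,
               ignore_attr = TRUE)
})

test_that("importance weights are prior/proposal density ratios", {
  prior <- prior_gaussian(0, matrix(1))
  proposal <- prior_gaussian(0, matrix(2))
  w <- importance_weights(matrix(0), prior, proposal)
  expect_equal(w, sqrt(2), tolerance = 1e-12)

  # proposal = prior: all weights 1
  box <- prior_box(c(-2, -2), c(2, 2))
  th <- prior_sample(box, 20, seed = 1)
  expect_equal(importance_weights(th, box, box), rep(1, 20))

  # outside the prior box: weight 0
  expect_equal(importance_weights(matrix(c(5, 0), 1), box, proposal = box), 0)
})

test_that("single-round SNPE recovers the conjugate posterior and amortizes", {
  cp <- conjugate_posterior_fixture()
  post <- cp$post
  expect_equal(post$rounds, 1L)
  expect_true(all(post$table$round == 1L))
  expect_true(all(post$table$weight == 1))

  th <- posterior_sample(post, 4000, seed = 1)
  expect_equal(colMeans(th), c(0, 0), tolerance = 0.1)
  expect_equal(apply(th, 2, var), c(0.5, 0.5), tolerance = 0.1)

  # amortization: the same network conditioned on a different observation
  # reproduces the closed form there too
  s2 <- estimator_sample(post$estimator, c(1, 1), 4000, seed = 2)
  expect_equal(colMeans(s2), c(0.5, 0.5), tolerance = 0.1)
})

test_that("posterior log-density is truncated to the prior support", {
  prior <- prior_box(c(-1, -1), c(1, 1))
  sim <- function(th, seed) { set.seed(seed); th + 0.3 * rnorm(2) }
  post <- run_snpe(prior, sim, identity, c(0, 0),
                   config = mdn_config(2, 2, hidden = c(16, 16),
                                       max_epochs = 60),
                   rounds = 1, n_per_round = 400, seed = 2)
  expect_identical(posterior_log_prob(post, c(2, 0)), -Inf)
  inside <- c(0.3, -0.2)
  expect_equal(posterior_log_prob(post, inside),
               estimator_log_prob(post$estimator, inside, post$x_o))
  # samples always lie inside the prior support
  th <- posterior_sample(post, 500, seed = 3)
  expect_true(all(prior_in_support(prior, th)))
})

test_that("posterior gradients match central finite differences", {
  cp <- conjugate_posterior_fixture()
  pts <- matrix(c(0.2, -0.4, 0.5, 0.1), 2, byrow = TRUE)
  g <- posterior_log_prob_grad(cp$post, pts)
  gn <- snpet:::numeric_grad(function(t) posterior_log_prob(cp$post, t), pts)
  expect_equal(g, gn, tolerance = 1e-4)
})

test_that("two-round SNPE-B is not worse than single-round at matched budget", {
  fx <- conjugate_fixture(2L)
  an <- fx$posterior(c(0, 0))
  rs <- an$sample(3000, seed = 55)
  kl_of <- function(post) {
    relative_kl(rs, an$log_density,
                function(t) posterior_log_prob(post, t),
                function(t) prior_log_density(fx$prior, t))$value
  }
  cfg <- mdn_config(2, 2, n_components = 1, hidden = c(30, 30))
  p1 <- run_snpe(fx$prior, fx$simulator, fx$extractor, c(0, 0), config = cfg,
                 rounds = 1, n_per_round = 2000, seed = 31)
  p2 <- run_snpe(fx$prior, fx$simulator, fx$extractor, c(0, 0), config = cfg,
                 rounds = 2, n_per_round = 1000, seed = 31)
  expect_true(all(p2$table$weight[p2$table$round == 1] == 1))
  expect_true(any(p2$table$weight[p2$table$round == 2] != 1))
  expect_lte(kl_of(p2), kl_of(p1) + 0.1)
})

test_that("invalid rows are excluded from training", {
  prior <- prior_box(c(-2), c(2))
  sim <- function(th, seed) { if (abs(th[1]) > 1.5) stop("outside valid regime"); th }
  post <- run_snpe(prior, sim, identity, 0,
                   config = mdn_config(1, 1, hidden = c(8, 8),
                                       max_epochs = 40),
                   rounds = 1, n_per_round = 300, seed = 12)
  tm <- snpet:::table_matrices(post$table)
  expect_gt(sum(!tm$valid), 0)
  expect_equal(post$estimator$n_train, sum(tm$valid))
})
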