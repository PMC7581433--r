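# Conditional density estimators: MDN sizing, log-densities, sampling,
# training, and the autoregressive-flow construction.

test_that("MDN sizing formula matches its closed form", {
  expect_identical(min_units(2, 8), 89L)
  expect_identical(min_units(1, 1), 2L)
  expect_identical(min_units(8, 9), 439L)
  expect_error(min_units(0, 5), "positive")
  expect_error(min_units(2, -1), "positive")
})

test_that("a pinned single-Gaussian MDN reproduces the standard normal", {
  mnet <- fixed_mdn(1, 1, logits = 0, mus = list(0), Ls = list(diag(1, 1)))
  mm <- snpet:::mdn_mixture(matrix(mnet$net$b[[3]], 1), matrix(0, 1, 1),
                            mnet$slots, 1, 1)
  expect_equal(mm$logq, dnorm(0, log = TRUE), tolerance = 1e-6)
})

test_that("an identity MAF evaluates the base density", {
  mnet <- identity_maf(2)
  lp <- snpet:::maf_log_prob_z(mnet, matrix(0, 1, 2), matrix(0, 1, 1))
  expect_equal(lp, 2 * dnorm(0, log = TRUE), tolerance = 1e-9)
})

test_that("trained estimators are normalized densities (quadrature)", {
  set.seed(11)
  x <- matrix(runif(1500, -2, 2), ncol = 1)
  th <- matrix(rnorm(1500, mean = x, sd = 1), ncol = 1)
  est <- train_estimator(th, mdn_config(1, 1, hidden = c(16, 16),
                                        max_epochs = 150), x = x, seed = 2)
  g <- seq(-8, 8, length.out = 2001)
  dens <- exp(estimator_log_prob(est, matrix(g, ncol = 1), 0.5))
  integral <- sum((dens[-1] + dens[-length(g)]) / 2) * diff(g)[1]
  expect_equal(integral, 1, tolerance = 0.01)

  # 2-D normalization for a MAF trained on a linear-Gaussian problem
  x2 <- matrix(runif(3000, -2, 2), ncol = 2)
  th2 <- x2 + matrix(rnorm(3000), ncol = 2)
  est2 <- train_estimator(th2, maf_config(2, 2, n_mades = 3,
                                          hidden = c(24, 24),
                                          max_epochs = 150),
                          x = x2, seed = 3)
  g2 <- seq(-6, 6, length.out = 121)
  gg <- as.matrix(expand.grid(g2, g2))
  lp <- estimator_log_prob(est2, gg, c(0, 0))
  integral2 <- sum(exp(lp)) * diff(g2)[1]^2
  expect_equal(integral2, 1, tolerance = 0.01)
})

test_that("MDN sampling matches a brute-force mixture sampler", {
  logits <- c(log(0.3), log(0.7))
  mus <- list(-2, 1.5)
  Ls <- list(diag(0.5, 1), diag(1.2, 1))
  mnet <- fixed_mdn(1, 2, logits, mus, Ls)
  est <- fixed_mdn_estimator(mnet)
  s1 <- estimator_sample(est, 0, 1e4, seed = 5)
  # oracle: direct ancestral sampling of the same mixture
  set.seed(99)
  k <- sample(1:2, 1e4, replace = TRUE, prob = c(0.3, 0.7))
  oracle <- rnorm(1e4, mean = unlist(mus)[k], sd = c(0.5, 1.2)[k])
  ks <- suppressWarnings(ks.test(as.numeric(s1), oracle))
  expect_lt(unname(ks$statistic), 0.03)

  # near-point-mass component recovers its mean
  mnet2 <- fixed_mdn(1, 1, 0, list(3.7), list(diag(1e-4, 1)))
  s2 <- estimator_sample(fixed_mdn_estimator(mnet2), 0, 500, seed = 1)
  expect_equal(mean(s2), 3.7, tolerance = 1e-3)

  # determinism under a fixed seed
  s3 <- estimator_sample(est, 0, 100, seed = 42)
  s4 <- estimator_sample(est, 0, 100, seed = 42)
  expect_identical(s3, s4)
})

test_that("training recovers a closed-form conditional mean", {
  set.seed(21)
  x <- matrix(runif(4000, -3, 3), ncol = 1)
  th <- matrix(rnorm(4000, mean = x, sd = 1), ncol = 1)
  est <- train_estimator(th, mdn_config(1, 1, hidden = c(24, 24),
                                        max_epochs = 400), x = x, seed = 4)
  for (x0 in c(-2, 0, 1.5)) {
    s <- estimator_sample(est, x0, 4000, seed = 8)
    expect_equal(mean(s), x0, tolerance = 0.1)
  }
  # loss trace descends
  expect_lte(tail(est$trace$train, 1), est$trace$train[1])
})

test_that("the weighted loss is invariant to row duplication with half weights", {
  set.seed(3)
  x <- matrix(rnorm(50), ncol = 1)
  th <- matrix(rnorm(50), ncol = 1)
  cfg <- mdn_config(1, 1, hidden = c(8, 8), max_epochs = 3)
  est <- train_estimator(th, cfg, x = x, seed = 1)
  lp <- estimator_log_prob(est, th, x)
  loss_orig <- sum(1 * -lp)
  loss_dup <- sum(0.5 * -c(lp, lp))
  expect_equal(loss_dup, loss_orig, tolerance = 1e-10)
})

test_that("seeded training is bit-reproducible", {
  set.seed(13)
  x <- matrix(rnorm(300), ncol = 1)
  th <- matrix(rnorm(300, x), ncol = 1)
  cfg <- mdn_config(1, 1, hidden = c(12, 12), max_epochs = 30)
  e1 <- train_estimator(th, cfg, x = x, seed = 77)
  e2 <- train_estimator(th, cfg, x = x, seed = 77)
  expect_identical(e1$net_obj$net$W, e2$net_obj$net$W)
  expect_identical(e1$trace, e2$trace)
})

test_that("MADE masks enforce the autoregressive property", {
  cfg <- maf_config(4, 2, n_mades = 1, hidden = c(16, 16))
  mnet <- snpet:::maf_init(cfg, seed = 5)
  net <- mnet$mades[[1]]$net
  x <- matrix(rnorm(6), 1)                      # 4 theta dims + 2 features
  base <- snpet:::mlp_forward(net, x, masks = mnet$masks)$out
  for (j in 1:4) {
    xp <- x
    xp[1, j] <- xp[1, j] + 1
    pert <- snpet:::mlp_forward(net, xp, masks = mnet$masks)$out
    # outputs (mu_i, alpha_i) for i <= j are bit-identical
    expect_identical(pert[1, 1:j], base[1, 1:j])
    expect_identical(pert[1, 4 + (1:j)], base[1, 4 + (1:j)])
  }
})

test_that("MAF forward transform round-trips through its inverse", {
  cfg <- maf_config(3, 2, n_mades = 4, hidden = c(16, 16))
  mnet <- snpet:::maf_init(cfg, seed = 9)
  set.seed(10)
  th <- matrix(rnorm(30), ncol = 3)
  xf <- matrix(rnorm(20), ncol = 2)[rep(1:10, length.out = 10), , drop = FALSE]
  f <- snpet:::maf_forward(mnet, th, xf)
  back <- snpet:::maf_inverse(mnet, f$z, xf)
  expect_equal(back, th, tolerance = 1e-6)
})

test_that("analytic MDN parameter gradients match finite differences", {
  mnet <- fixed_mdn(2, 2, c(0.2, -0.1),
                    list(c(0, 0), c(1, -1)),
                    list(matrix(c(1, 0, 0.3, 0.8), 2, byrow = TRUE),
                         matrix(c(0.6, 0, -0.2, 1.1), 2, byrow = TRUE)))
  est <- fixed_mdn_estimator(mnet)
  th <- matrix(c(0.4, -0.3), 1)
  g <- estimator_log_prob_grad(est, th, 0)
  gn <- snpet:::numeric_grad(function(t) estimator_log_prob(est, t, 0), th)
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("undersized hidden layers trigger the sizing warning", {
  expect_warning(mdn_config(8, 7, n_components = 2, hidden = c(50, 50)),
                 "minimum")
})

test_that("a fixed embedding compresses image-valued features", {
  # 16x16 receptive-field model: the 257-dim (N, pixelwise STA) features
  # are projected through a fixed random embedding before the network
  grid <- gabor_grid(16L)
  set.seed(40)
  movie <- matrix(rnorm(300 * 256), 300, 256)
  proj <- matrix(rnorm(257 * 20, sd = 1 / sqrt(257)), 257, 20)
  embed <- function(X) X %*% proj
  prior <- gabor_prior("natural")
  sim <- function(th, seed) simulate_gabor_glm(th, movie, grid, seed = seed)
  ext <- function(z) as.numeric(sta_summary(z, movie))
  tab <- run_simulations(prior, sim, ext, 400, seed = 21)
  # rate-overflow draws are flagged invalid, the rest train the estimator
  expect_gt(sum(tab$valid), 100)
  expect_lt(sum(tab$valid), 400)
  cfg <- suppressWarnings(mdn_config(9, 20, hidden = c(30, 30),
                                     max_epochs = 60, embedding = embed))
  est <- train_estimator(tab, cfg, seed = 2)
  x_raw <- snpet:::table_matrices(tab)$x[1, ]
  lp <- estimator_log_prob(est, prior_sample(prior, 3, seed = 5), x_raw)
  expect_true(all(is.finite(lp)))
  s <- estimator_sample(est, x_raw, 50, seed = 6)
  expect_equal(dim(s), c(50L, 9L))
})
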