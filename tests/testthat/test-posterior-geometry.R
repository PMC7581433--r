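# Conditional correlations, high-probability paths, and orthogonal
# perturbations, checked against analytic Gaussian oracles.

test_that("conditional correlation recovers an analytic correlation", {
  rho <- 0.8
  post <- analytic_posterior(c(0, 0), matrix(c(1, rho, rho, 1), 2),
                             lower = c(-4, -4), upper = c(4, 4))
  g <- conditional_grid(post, c(0, 0), dims = c(1, 2))
  expect_equal(conditional_correlation(g), rho, tolerance = 0.02)

  # independent product density: zero correlation
  post0 <- analytic_posterior(c(0, 0), diag(c(1, 2)),
                              lower = c(-5, -6), upper = c(5, 6))
  g0 <- conditional_grid(post0, c(0, 0), dims = c(1, 2))
  expect_equal(conditional_correlation(g0), 0, tolerance = 0.01)

  # mirroring one axis negates the correlation
  gm <- g
  gm$density <- g$density[nrow(g$density):1, ]
  expect_equal(conditional_correlation(gm), -conditional_correlation(g),
               tolerance = 1e-12)
})

test_that("averaged conditional correlations equal Gaussian partial correlations", {
  S <- matrix(c(1.0, 0.6, 0.2,
                0.6, 1.5, -0.4,
                0.2, -0.4, 0.8), 3, 3)
  post <- analytic_posterior(c(0, 1, -1), S,
                             lower = c(-6, -6, -6), upper = c(6, 8, 5))
  avg <- average_conditional_corr(post, n_conditions = 10, seed = 3)
  # oracle: partial correlations from the precision matrix
  P <- solve(S)
  pc <- -P / sqrt(outer(diag(P), diag(P)))
  diag(pc) <- 1
  expect_equal(avg$mean, pc, tolerance = 0.05)
  expect_equal(avg$mean, t(avg$mean))
  expect_equal(diag(avg$mean), rep(1, 3))

  # for a Gaussian, the conditional correlation is condition-independent
  sds <- apply(avg$per_condition, c(1, 2), sd)
  expect_lt(max(sds[upper.tri(sds)]), 0.02)

  # a single conditioning point is its own average
  one <- average_conditional_corr(post, n_conditions = 1, seed = 5)
  expect_equal(one$mean, one$per_condition[, , 1], ignore_attr = TRUE)
})

test_that("path evaluation honors endpoints, midpoints and basis linearity", {
  ts <- c(1, -2, 0.5)
  tg <- c(-1, 0.3, 2)
  path <- path_parameterization(ts, tg, K = 2)
  set.seed(4)
  path$alpha <- matrix(rnorm(12, sd = 3), 3, 4)   # d x 2K
  expect_equal(as.numeric(path_eval(path, 0)), ts, tolerance = 1e-12)
  expect_equal(as.numeric(path_eval(path, 1)), tg, tolerance = 1e-12)

  straight <- path_parameterization(ts, tg, K = 2)
  expect_equal(as.numeric(path_eval(straight, 0.5)), (ts + tg) / 2)

  # one nonzero coefficient deviates by exactly its basis function
  p1 <- path_parameterization(ts, tg, K = 2)
  p1$alpha[2, 1] <- 1.7
  s <- c(0.25, 0.6)
  dev <- path_eval(p1, s) - path_eval(straight, s)
  expect_equal(dev[, 2], 1.7 * sin(pi * s), tolerance = 1e-12)
  expect_equal(dev[, c(1, 3)], matrix(0, 2, 2), tolerance = 1e-12)
})

test_that("the path loss reduces to length x constant under a flat density", {
  flat <- list(log_prob = function(th) rep(log(0.2), nrow(th)))
  ts <- c(0, 0); tg <- c(3, 4)
  path <- path_parameterization(ts, tg)
  expect_equal(path_loss(path, flat), -log(0.2) * 5, tolerance = 1e-9)
  # shrinking the endpoints together drives the loss to zero
  tiny <- path_parameterization(ts, ts + 1e-9)
  expect_lt(path_loss(tiny, flat), 1e-7)
  # doubling all coordinates doubles the loss
  path2 <- path_parameterization(2 * ts, 2 * tg)
  expect_equal(path_loss(path2, flat), 2 * path_loss(path, flat),
               tolerance = 1e-9)
})

test_that("path optimization raises the worst log-density on a curved ridge", {
  # banana-shaped ridge: high density along theta2 = theta1^2
  banana <- list(
    log_prob = function(th) -0.5 * ((th[, 2] - th[, 1]^2)^2 / 0.1^2 +
                                    th[, 1]^2 / 4),
    grad = function(th) {
      d <- (th[, 2] - th[, 1]^2)
      cbind(d / 0.1^2 * 2 * th[, 1] - th[, 1] / 4, -d / 0.1^2)
    }
  )
  straight <- path_parameterization(c(-1.5, 2.25), c(1.5, 2.25), K = 2)
  opt <- optimize_path(straight, banana, steps = 400, lr = 5e-3)
  pd_s <- snpet:::path_discretize(straight)
  pd_o <- snpet:::path_discretize(opt)
  expect_gt(min(banana$log_prob(pd_o$G)), min(banana$log_prob(pd_s$G)))
  # endpoints are bit-exact after optimization
  expect_identical(opt$theta_s, straight$theta_s)
  expect_identical(opt$theta_g, straight$theta_g)
  expect_equal(path_eval(opt, c(0, 1)),
               rbind(straight$theta_s, straight$theta_g), tolerance = 1e-12)

  # symmetric endpoints on an isotropic Gaussian: the straight line is
  # already optimal, coefficients stay near zero
  iso <- analytic_posterior(c(0, 0), diag(1, 2))
  sym <- path_parameterization(c(-1, 0), c(1, 0), K = 2)
  opt2 <- optimize_path(sym, iso, steps = 200, lr = 1e-3)
  expect_lt(max(abs(opt2$alpha)), 0.05)
})

test_that("gradient-projection steps are orthogonal and descend", {
  post <- analytic_posterior(c(0, 0, 0), diag(c(1, 4, 0.25)))
  set.seed(2)
  for (i in 1:20) {
    n <- rnorm(3)
    theta <- rnorm(3)
    d <- orthogonal_step(post, theta, n)
    expect_lt(abs(sum(n * d)), 1e-10)
  }
  # the projector annihilates the tangent itself
  n <- c(1, 2, -1)
  P <- diag(3) - outer(n, n) / sum(n^2)
  expect_equal(as.numeric(P %*% n), rep(0, 3), tolerance = 1e-12)

  # log-density decreases monotonically along the orthogonal trajectory
  traj <- orthogonal_path(post, theta0 = c(0.5, 0.1, -0.2),
                          tangent = c(1, 1, 1), total_distance = 2,
                          step_size = 0.05)
  expect_true(all(diff(traj$log_prob) < 0))
})
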