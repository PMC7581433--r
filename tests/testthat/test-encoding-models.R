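# Linear-nonlinear encoding models: temporal Bernoulli GLM, sufficient
# statistics, the smoothness prior, and the Gabor Poisson GLM.

test_that("temporal GLM firing probabilities follow the sigmoid link", {
  V <- glm_design(seed = 1)
  # zero filter, zero bias: each bin fires with probability 1/2
  counts <- vapply(1:300, function(i)
    sum(simulate_temporal_glm(rep(0, 10), V, seed = i)), numeric(1))
  expect_equal(mean(counts), 50, tolerance = 1.5)

  # strongly negative bias: silence
  z <- simulate_temporal_glm(c(-20, rep(0, 9)), V, seed = 2)
  expect_equal(sum(z), 0)

  # per-bin empirical rates match the closed form within 3 standard errors
  theta <- c(0.2, 0.5, -0.3, 0.8, 0, 0.2, -0.5, 0.1, 0.4, -0.2)
  Vs <- glm_design(T_bins = 25L, seed = 3)
  p_true <- snpet:::sigmoid(as.numeric(Vs %*% theta[-1]) + theta[1])
  nrep <- 4000L
  Z <- vapply(seq_len(nrep), function(i)
    simulate_temporal_glm(theta, Vs, seed = 100 + i), numeric(25))
  p_hat <- rowMeans(Z)
  se <- sqrt(p_true * (1 - p_true) / nrep)
  expect_true(all(abs(p_hat - p_true) <= 4 * se))
  expect_gte(mean(abs(p_hat - p_true) <= 3 * se), 0.9)
})

test_that("spike count and STA are the model's sufficient summaries", {
  V <- glm_design(seed = 7)
  z <- rep(0L, 100); z[37] <- 1L
  s <- sta_summary(z, V)
  expect_equal(s[1], 1)
  expect_equal(s[-1], V[37, ], ignore_attr = TRUE)

  z0 <- rep(0L, 100)
  s0 <- sta_summary(z0, V)
  expect_equal(as.numeric(s0), rep(0, 10))
  expect_false(attr(s0, "valid"))

  # two spike trains with equal (N, Vz) give identical summaries
  z1 <- rep(0L, 100); z1[c(5, 20)] <- 1L
  V2 <- V; V2[5, ] <- V[20, ]; V2[20, ] <- V[5, ]
  expect_equal(sta_summary(z1, V), sta_summary(z1, V2))
})

test_that("the smoothness operator annihilates linear ramps in its interior", {
  sp <- smoothness_prior(9, sigma = 0.5)
  ramp <- seq(-1, 1, length.out = 9)
  v <- crossprod(sp$F) %*% ramp
  expect_equal(as.numeric(v[3:7]), rep(0, 5), tolerance = 1e-12)
  expect_no_error(chol(sp$Sigma))
})

test_that("the Gabor filter obeys its analytic structure", {
  grid <- gabor_grid(41L)
  p <- c(gain = 1.3, freq = 2, aspect = 1.5, width = 1, phase = 0,
         angle = 0.7, x = 0, y = 0, beta = 0)
  h <- gabor_filter(p, grid)
  centre <- which(abs(grid$gx) < 1e-9 & abs(grid$gy) < 1e-9)
  expect_equal(h[centre], 1.3, tolerance = 1e-12)

  # with zero phase, rotating the filter by 180 degrees changes nothing
  p2 <- p; p2["angle"] <- p["angle"] + pi
  expect_equal(gabor_filter(p2, grid), h, tolerance = 1e-12)

  # envelope dominance: |h| decays monotonically along the minor axis
  # beyond 3 sigma (dense 1-D probe through the center)
  sg <- snpet:::gabor_sigma(2, 1)
  tvals <- seq(3 * sg, 0.99, length.out = 200)
  vals <- vapply(tvals, function(tv) {
    gx <- matrix(tv * sin(p["angle"]), 1, 1)
    gy <- matrix(tv * cos(p["angle"]), 1, 1)
    abs(gabor_filter(p, list(gx = gx, gy = gy, n = 1L)))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("Gabor transforms invert exactly and map midpoints to zero", {
  set.seed(8)
  nat <- c(gain = 0.7, freq = 1.2, aspect = 0.9, width = 1.4,
           phase = pi / 2, angle = pi, x = 0, y = 0.3, beta = -0.5)
  eta <- transform_gabor(nat)
  expect_equal(eta[["phase"]], 0, tolerance = 1e-12)   # midpoint of (0, pi)
  expect_equal(eta[["x"]], 0, tolerance = 1e-12)       # midpoint of (-1, 1)
  back <- untransform_gabor(eta)
  expect_equal(back, nat, tolerance = 1e-10)
  expect_error(transform_gabor(replace(nat, "phase", 0)), "bounds")
})

test_that("Gabor prior draws always land inside the parameter bounds", {
  pr <- gabor_prior("natural")
  th <- prior_sample(pr, 2000, seed = 3)
  expect_true(all(th[, 1:4] > 0))
  expect_true(all(th[, 5] > 0 & th[, 5] < pi))
  expect_true(all(th[, 6] > 0 & th[, 6] < 2 * pi))
  expect_true(all(abs(th[, 7:8]) < 1))
})

test_that("the Gabor GLM is Poisson with an exponential link", {
  grid <- gabor_grid(16L)
  set.seed(4)
  movie <- matrix(rnorm(200 * 256), 200, 256)
  # zero-gain filter reduces to the bias-only rate
  p0 <- c(gain = 1e-12, freq = 1, aspect = 1, width = 1, phase = 1,
          angle = 1, x = 0, y = 0, beta = 0)
  z <- unlist(lapply(1:50, function(i)
    simulate_gabor_glm(p0, movie, grid, seed = i)))
  expect_equal(mean(z), 1, tolerance = 0.05)

  p2 <- p0; p2["beta"] <- log(2)
  z2 <- unlist(lapply(1:50, function(i)
    simulate_gabor_glm(p2, movie, grid, seed = 100 + i)))
  expect_equal(mean(z2), 2, tolerance = 0.1)

  # dispersion: per-bin variance tracks the per-bin mean
  p3 <- c(gain = 0.5, freq = 1.5, aspect = 1, width = 1, phase = 1,
          angle = 2, x = 0.2, y = -0.1, beta = 0)
  small <- movie[1:12, , drop = FALSE]
  Z <- vapply(1:6000, function(i)
    simulate_gabor_glm(p3, small, grid, seed = 1000 + i), numeric(12))
  m <- rowMeans(Z); v <- apply(Z, 1, var)
  # var of the variance estimate of a Poisson: (2 mu^2 + mu)/n approx
  se <- sqrt((2 * m^2 + m) / ncol(Z))
  expect_true(all(abs(v - m) <= 4 * se))

  expect_error(
    simulate_gabor_glm(replace(p3, "beta", 100), small, grid, seed = 1),
    "overflow")
})
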