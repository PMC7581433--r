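# The non-inactivating potassium-channel family: kinetics curves,
# voltage-clamp integration, and the PCA summary-feature pipeline.

test_that("steady-state activation is a correct, monotone sigmoid", {
  expect_equal(omni_steady_state(5 / 0.5, 0.5, 5), 0.5)     # V = theta2/theta1
  expect_equal(omni_steady_state(1e4, 0.5, 5), 1)           # saturating limit
  th <- prior_sample(omnimodel_prior(), 100, seed = 2)
  V <- seq(-120, 120, by = 1)
  mono_ok <- vapply(1:100, function(i) {
    m <- omni_steady_state(V, th[i, 1], th[i, 2])
    all(diff(m) >= 0) && m[1] < m[length(m)]
  }, logical(1))
  expect_true(all(mono_ok))
})

test_that("the time-constant curve is positive with the stated peak", {
  th <- c(10, 500, 0.1, 0.01, 0.2, 0.02)   # theta3..theta8
  expect_equal(as.numeric(omni_time_constant(10, th)), 250) # V = theta3: theta4/2
  # positivity across prior draws and voltages
  draws <- prior_sample(omnimodel_prior(), 1000, seed = 5)
  V <- runif(1000, -120, 120)
  taus <- vapply(1:1000, function(i)
    as.numeric(omni_time_constant(V[i], draws[i, 3:8])), numeric(1))
  expect_true(all(taus > 0))
  # peak location on a 1 mV grid agrees with a dense-grid argmax
  set.seed(8)
  coarse <- seq(-120, 120, by = 1)
  dense <- seq(-120, 120, by = 0.01)
  for (i in sample(1000, 20)) {
    tau_c <- omni_time_constant(coarse, draws[i, 3:8])
    tau_d <- omni_time_constant(dense, draws[i, 3:8])
    expect_lt(abs(coarse[which.max(tau_c)] - dense[which.max(tau_d)]), 1)
  }
})

test_that("voltage-clamp integration matches the exponential relaxation", {
  theta <- c(0.2, 1, 0, 200, 0.05, 0.005, 0.05, 0.005)
  # command clamped at the reversal potential: zero current everywhere
  proto0 <- list(name = "const", dt = 0.05, v = rep(-107, 2000))
  tr0 <- simulate_current(theta, proto0, seed = 1, noise_sd = 0)
  expect_true(all(tr0 == 0))

  # constant step without noise: m(t) relaxes to m_inf within 5 tau at 1%,
  # following the closed-form exponential along the way
  v0 <- 0
  tau <- as.numeric(omni_time_constant(v0, theta[3:8]))
  nstep <- ceiling(6 * tau / 0.05)
  raw <- snpet:::omnimodel_trace_cpp(theta, rep(v0, nstep), 0.05, -107, 0, 1L)
  m_traj <- raw / (v0 + 107)
  tm <- (seq_along(m_traj) - 1) * 0.05
  m_inf <- omni_steady_state(v0, theta[1], theta[2])
  m_exp <- m_inf + (m_traj[1] - m_inf) * exp(-tm / tau)
  expect_equal(m_traj, m_exp, tolerance = 1e-3)
  at5 <- which.min(abs(tm - 5 * tau))
  expect_equal(m_traj[at5] / m_inf, 1, tolerance = 0.01)

  # halving dt changes the trace by < 0.5% RMS
  protoA <- list(name = "s", dt = 0.05, v = rep(20, 4000))
  protoB <- list(name = "s", dt = 0.025, v = rep(20, 8000))
  trA <- simulate_current(theta, protoA, seed = 1, noise_sd = 0, store_every = 4L)
  trB <- simulate_current(theta, protoB, seed = 1, noise_sd = 0, store_every = 8L)
  rel_rms <- sqrt(mean((trA - trB)^2)) / sqrt(mean(trB^2))
  expect_lt(rel_rms, 0.005)
})

test_that("the feature pipeline yields 55 orthonormal-basis coefficients", {
  basis <- omni_basis_fixture()
  th <- prior_sample(omnimodel_prior(), 1, seed = 9)[1, ]
  set.seed(31)
  traces <- simulate_channel(th)
  f <- channel_features(traces, basis)
  expect_length(f, 55L)
  expect_true(all(is.finite(f)))

  for (pn in names(basis$basis)) {
    b <- basis$basis[[pn]]
    # loadings are orthonormal within a protocol
    expect_equal(crossprod(b$loadings), diag(1, 10), tolerance = 1e-8)
    # a trace equal to a basis vector maps to an indicator coefficient
    # pattern (up to the offset regressor)
    fake <- traces
    fake[[pn]] <- b$loadings[, 3]
    ff <- channel_features(fake, basis)
    block <- ff[(match(pn, names(basis$basis)) - 1) * 11 + 1:10]
    expect_equal(block[3], 1, tolerance = 1e-6)
    expect_equal(block[-3], rep(0, 9), tolerance = 1e-6)
    break
  }

  # projecting a training-set-like trace onto 10 components explains at
  # least the basis' stated variance share
  expect_true(all(vapply(basis$basis, function(b) b$explained, numeric(1)) > 0.9))
})

test_that("PCA basis fitting enforces its preconditions", {
  X <- matrix(rnorm(40 * 30), 40, 30)
  expect_error(fit_pca_basis(list(a = X)), ">= 50")
  Xr <- matrix(1, 60, 30) + outer(rnorm(60), c(1, rep(0, 29)))
  expect_error(fit_pca_basis(list(a = Xr)), "rank")
})
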