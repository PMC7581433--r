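# Shared fixtures, cached so expensive objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 2-D conjugate-Gaussian problem with a trained single-round posterior at
# x_o = (0, 0); closed-form posterior N(0, I/2).
conjugate_posterior_fixture <- function() {
  cached("conjugate_post", {
    fx <- conjugate_fixture(2L)
    post <- run_snpe(fx$prior, fx$simulator, fx$extractor, x_o = c(0, 0),
                     config = mdn_config(2, 2, n_components = 1,
                                         hidden = c(30, 30)),
                     rounds = 1, n_per_round = 3000, seed = 7)
    list(fx = fx, post = post)
  })
}

# An MDN whose output layer is pinned to a fixed mixture regardless of x:
# zero all weights, then set the output biases.
fixed_mdn <- function(n_params, n_components, logits, mus, Ls) {
  cfg <- suppressWarnings(mdn_config(n_params, 1, n_components,
                                     hidden = c(8, 8)))
  mnet <- snpet:::mdn_init(cfg, seed = 1)
  for (l in seq_along(mnet$net$W)) {
    mnet$net$W[[l]][] <- 0
    mnet$net$b[[l]][] <- 0
  }
  nl <- length(mnet$net$b)
  b <- mnet$net$b[[nl]]
  s <- mnet$slots
  b[s$logits] <- logits
  inv_softplus <- function(y) log(expm1(y))
  for (k in seq_len(n_components)) {
    b[s$mu[[k]]] <- mus[[k]]
    b[s$diag[[k]]] <- inv_softplus(diag(Ls[[k]]) - 1e-6)
    if (s$noff > 0) b[s$off[[k]]] <- Ls[[k]][s$ij]
  }
  mnet$net$b[[nl]] <- b
  mnet
}

# Wrap a pinned MDN as a full estimator with identity normalization.
fixed_mdn_estimator <- function(mnet, n_features = 1L) {
  D <- mnet$config$n_params
  structure(list(
    config = mnet$config,
    net_obj = mnet,
    zs_theta = list(mean = rep(0, D), sd = rep(1, D)),
    zs_x = list(mean = rep(0, n_features), sd = rep(1, n_features)),
    trace = list(train = numeric(0), val = numeric(0)),
    seed = 1L, n_train = 0L
  ), class = c("mdn_estimator", "density_estimator"))
}

# MAF with all weights zero: every bijection is the identity.
identity_maf <- function(n_params, n_features = 1L, n_mades = 2L) {
  cfg <- maf_config(n_params, n_features, n_mades = n_mades, hidden = c(8, 8))
  mnet <- snpet:::maf_init(cfg, seed = 1)
  for (t in seq_along(mnet$mades)) {
    for (l in seq_along(mnet$mades[[t]]$net$W)) {
      mnet$mades[[t]]$net$W[[l]][] <- 0
      mnet$mades[[t]]$net$b[[l]][] <- 0
    }
  }
  mnet
}

# PCA feature basis for the channel model, shared between test files.
omni_basis_fixture <- function() {
  cached("omni_basis", omnimodel_pca_basis(n_train = 60L, seed = 4))
}

# Synthetic Hodgkin-Huxley observation used across the HH tests: a
# regular two-spike response in a stable regime.
hh_observation_fixture <- function() {
  cached("hh_obs", {
    theta_star <- c(50, 5, 0.1, 0.07, 600, 60, 0.1, 70)
    mod <- hh_model(feature_set = 7L)
    x_o <- mod$extractor(mod$simulator(theta_star, 4242))
    list(theta_star = theta_star, mod = mod, x_o = x_o)
  })
}

# Hodgkin-Huxley posteriors conditioned on growing feature subsets,
# shared between the narrowing and predictive-check tests.
hh_posterior_fixture <- function(k) {
  ob <- hh_observation_fixture()
  cached(paste0("hh_post_", k),
         run_hh_inference(ob$x_o[1:k], budget = 4000, feature_set = k,
                          seed = 21))
}

# Reference posterior and observation for the temporal GLM, shared by the
# baseline-comparison tests.
glm_reference_fixture <- function() {
  cached("glm_ref", {
    prior <- glm_temporal_prior()
    V <- glm_design(seed = 42)
    theta_true <- prior_sample(prior, 1, seed = 99)[1, ]
    z_o <- simulate_temporal_glm(theta_true, V, seed = 123)
    x_o <- as.numeric(sta_summary(z_o, V))
    mc <- mcmc_reference(function(th) glm_log_posterior(th, z_o, V, prior),
                         init = rep(0, 10), n_samples = 20000, burn = 5000,
                         seed = 5)
    ref <- analytic_posterior(colMeans(mc$samples), cov(mc$samples))
    list(prior = prior, V = V, theta_true = theta_true, z_o = z_o,
         x_o = x_o, ref = ref,
         simulator = function(th, seed) simulate_temporal_glm(th, V, seed = seed),
         extractor = function(z) as.numeric(sta_summary(z, V)))
  })
}
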