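model: glm_temporal
description: Temporal Bernoulli GLM (9-tap filter + bias), 100 time bins.
prior:
  kind: gaussian-smoothness
  sigma: 0.5
  beta_var: 1.0
simulation:
  t_bins: 100
  n_taps: 9
inference:
  estimator: mdn
  n_components: 1
  hidden: [50, 50]
  default_budget: 10000
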