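model: gabor
description: Gabor-parameterized Poisson GLM receptive-field model.
prior:
  kind: gaussian-transformed
  sd_transformed: [0.5, 0.5, 0.5, 0.5, 1.9, 1.78, 1.78, 1.78]
  bias_mean: -0.57
  bias_var: 1.63
simulation:
  grid: 16
  full_grid: 41
  dt_s: 0.025
inference:
  estimator: mdn
  n_components: 1
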