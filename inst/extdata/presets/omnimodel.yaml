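model: omnimodel
description: Non-inactivating K+ channel family under five noisy voltage-clamp protocols.
prior:
  kind: box
  lower: [0, -10, -120, 0, 0, 0, 0, 0]
  upper: [1, 10, 120, 2000, 0.5, 0.05, 0.5, 0.05]
  names: [theta1, theta2, theta3, theta4, theta5, theta6, theta7, theta8]
simulation:
  dt_ms: 0.025
  noise_sd_mv: 0.5
  e_k_mv: -107
features:
  per_protocol: 11
  total: 55
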