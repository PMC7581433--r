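model: hh
description: Stochastic single-compartment Hodgkin-Huxley neuron (Na, Kd, M, leak).
prior:
  kind: box
  lower: [0.5, 1.0e-4, 1.0e-4, 1.0e-4, 50, 40, 1.0e-4, 35]
  upper: [80, 15, 0.6, 0.6, 3000, 90, 0.15, 100]
  names: [gbar_Na, gbar_K, g_leak, gbar_M, tau_max, V_T, sigma, E_leak]
constants:
  e_na_mv: 53
  e_k_mv: -107
  c_m: 1.0
protocol:
  t_total_ms: 120
  t_on_ms: 10
  t_off_ms: 90
  i_amp: 2.0
  dt_ms: 0.025
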