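model: stg
description: Three-neuron pyloric circuit (AB/PD, LP, PY) with 7 graded synapses.
prior:
  kind: box-with-log-synapses
  synapse_range_ns: [0.01, 1000]
  synapse_ablp_range_ns: [0.01, 10000]
simulation:
  duration_ms: 3000
  full_duration_ms: 10000
  dt_ms: 0.025
  noise_sd: 0.001
  transient_ms: 1000
synapses:
  glutamatergic: [AB-LP, AB-PY, LP-AB, LP-PY, PY-LP]
  cholinergic: [PD-LP, PD-PY]
  e_s_glut_mv: -70
  e_s_chol_mv: -80
features:
  rhythm: 15
  plateau: 3
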