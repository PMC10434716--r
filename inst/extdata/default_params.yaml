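# Calibrated single parameter set shared by all experiment simulations.
# Activation is relative to the visibility threshold at zero; space in
# field units (6.6 arcmin = 8 units); time in ms.
field:
  tau_u: 20
  tau_v: 10
  h_u: -5.02
  h_v: -1.6
  beta: 6
  w_uu_amp: 6.5
  w_uu_width: 6
  w_uv_amp: 12
  w_uv_width: 12
  w_vu_amp: 6
  w_vu_width: 10
trace:
  trace_build_tau: 400
  trace_decay_tau: 30000
  trace_gain: 14
  trace_spread: 25
  trace_sat: 0.06
adaptation:
  adapt_tau: 1500
  adapt_decay_tau: 10000
  adapt_gain: 2.6
  adapt_spread: 20
noise:
  noise_slow_tau: 20000
  noise_slow_amp: 0.4
  noise_fast_amp: 0.05
integration:
  input_width: 6
  dt: 1
  n_points: 201
  spacing: 1
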