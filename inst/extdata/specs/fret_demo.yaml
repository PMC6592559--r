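treatments:
  HL3:
    role: negative_control
    kinetics:
      t_app: 100.0
      a_slow: 0.0
      tau_slow: 200.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  NKH477:
    role: positive_control
    kinetics:
      t_app: 100.0
      a_slow: 2.22222222222222188
      tau_slow: 150.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  PDF:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 0.95238095238095311
      tau_slow: 200.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  PDF_TTX:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 0.95238095238095311
      tau_slow: 200.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  sNPF:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 0.95238095238095311
      tau_slow: 200.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  sNPF_TTX:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 0.95238095238095311
      tau_slow: 200.0
      a_fast: 0.0
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  sNPF_PDF:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 1.39534883720930147
      tau_slow: 200.0
      a_fast: 0.64828253507498734
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: no
  sNPF_PDF_half:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 0.95238095238095311
      tau_slow: 200.0
      a_fast: 0.39215686274509837
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: 400.0
      tau_decline: 600.0
      ttx_blocks_fast: no
  sNPF_PDF_TTX:
    role: experimental
    kinetics:
      t_app: 100.0
      a_slow: 1.22065727699530413
      tau_slow: 200.0
      a_fast: 0.64828253507498734
      tau_fast_rise: 10.0
      tau_fast_decay: 40.0
      t_decline: .inf
      tau_decline: 300.0
      ttx_blocks_fast: yes
n_brains: 5
neurons_per_brain: 4
frame_rate: 0.20000000000000001
duration: 1000.0
c0: 1000.0
y0: 2000.0
g0: 1000.0
gain: 0.05
spillover_k: 0.35699999999999998
bg_level: 50.0
bg_drift: 0.02
noise_sd_frac: 0.002
bleach_tau: .inf
neuron_cv: 0.10000000000000001
seed: 20190521
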