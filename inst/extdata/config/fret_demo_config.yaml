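mode: fret
spec: specs/fret_demo.yaml
seed: 2.0190521e+07
windows:
  baseline:
  - 0.0
  - 100.0
  long:
  - 100.0
  - 1000.0
  short:
  - 100.0
  - 200.0
spillover_k: 0.357
n_boot: 2000.0
plots: yes
synergy:
  combined: sNPF_PDF
  single_a: sNPF
  single_b: PDF
  window: short
out_dir: ipcquant_demo_out
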