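# Demo: two simulated genotypes under a flash protocol, burst decomposition
# and a group comparison of the RRP readout.
seed: 42
protocol:
  kind: flash
  ca_pre: 0.5
  ca_post: 20
  t_flash: 0.5
  duration: 1.7
  dt: 0.002
groups:
  - name: ko
    n_cells: 3
    cv: 0.15
    params:
      B1: 90
      B2: 80
  - name: wt
    n_cells: 3
    cv: 0.15
    params:
      B1: 220
      B2: 150
analyses: [flash, compare]
compare_field: RRP
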