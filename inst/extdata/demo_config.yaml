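# Small demonstration configuration for run_pipeline(): two tumor clones
# well separated by private events, 150 cells at 0.02X.
simulation:
  n_clones: 2
  n_truncal_events: 20
  n_private_events: 8
  n_cells: 150
clones:
  error_rate: 0.12
seed: 42
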