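# Desk-scale demo configuration for the pipeline CLI.
# Sections mirror synthetic_config(), listing_sim_config() and
# model_config(); omitted fields keep their defaults.
synthetic:
  lattice_rows: 8
  lattice_cols: 8
listings:
  n_taro_true: 20
  n_tro_only: 15
  n_aro_only: 15
model:
  n_iter: 2000
  n_burnin: 1000
  n_chains: 2
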