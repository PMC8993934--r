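# Small demonstration configuration: a three-site synthetic world, two
# years per site, and a reduced network so the full pipeline completes in
# well under a minute. Values mirror default_config(); see ?default_config.
seed: 7
world:
  n_sites: 3
  n_years: 2
  veg_class: short
  noise_sd: 0.05
  n_rows: 2000
model:
  hidden: [32, 32]
  max_epochs: 60
  patience: 10
  min_rows: 200
run:
  n_days: 365
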