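seed: 42.0
sessions:
  n_per_condition: 1.0
  n_blocks: 8.0
block_spec:
  min_trials: 30.0
  switch_criterion: 0.9
  switch_window: 12.0
  max_trials: 80.0
agent:
  learning_rate: 0.3
  inverse_temperature: 6.0
  decay: 0.1
  initial_value: 0.5
units:
  n_per_condition: 9.0
  baseline_rate: 8.0
  tuned_fraction: 0.3
  tuning_variable: rpe_signed
  gain_drug: 0.4
  gain_control: 0.2
  scheme: cortical
  prop_ns: 0.3
stats:
  alpha: 0.05
  n_perm: 200.0
  min_trials: 30.0
  min_units: 3.0
epoch: feedback
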