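# Default run configuration: a study-shaped synthetic cohort on the default
# 120-trial task. Omitted keys fall back to package defaults; the generating
# effect map is the package default (see ?default_effect_map).
cohort:
  n_baseline: 208
  cohort_split: 0.5
  waves: 5
  wave_spacing: 0.75
  retention: [208, 157, 135, 98, 73]
  maternal_hx_prev: 0.36
  female_prob: 0.59
  iq_mean: 101.8
  iq_sd: 15
  onsite_prob: [1, 1, 1, 0.89, 0.41]
  dropout: mar
task:
  n_trials: 120
  starting_bank: 2000
  timeout_seconds: 4
  version: 1
  timeout_prob: 0
model:
  outcome_scale: 100
  fictive_updating: true
  fictive_attenuation: 3
fit:
  backend: map_eb
  tolerance: 0.001
  max_iterations: 20
  sd_floor: 0.05
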