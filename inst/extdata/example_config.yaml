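# Example synthetic-cohort pipeline configuration.
# Cohort sizes mirror the study design (28 controls scanned once, 23
# patients scanned early and late, 90 atlas regions); the search and
# resampling efforts are desk-scale defaults.
synthetic:
  n_controls: 28
  n_patients: 23
  n_regions: 90
  early_attenuation: 0.7
  recovery_gain: 1.5
  noise_sd: 0.5
  lesion_grid: [45, 54, 45]
top_k: 40
garf:
  pop_size: 30
  generations: 12
  num_trees: 200
  k_folds: 5
  fold_mode: grouped
filter_alpha: 0.05
regression_alpha: 0.05
bootstrap_runs: 200
bootstrap_repeats: 3
null_runs: 200
lesion_min_patients: 3
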