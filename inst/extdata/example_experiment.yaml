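# Example experiment configuration for run_experiment() /
# read_experiment_config(). Any field omitted falls back to the defaults
# of default_experiment_config() and cohort_config().
seed: 1
cohort:
  n_subjects: 38          # subjects; two hemispheres each by default
  p_type1: 0.38           # probability a hemisphere shows the connected type
  concordance: 0.71       # inter-hemispheric type concordance
  jitter_sd: 1.5          # mm, rigid per-structure translation SD per axis
  connection_gap: 3       # mm, minimum RS / CS proper separation in Type 2
  bridge_radius: 1.5      # mm, Type-1 connecting segment radius
  tube_radius: 2          # mm, sulcal tube radius
  age_range: [7, 17]      # years, uniform
analysis:
  fractions: [0.05, 0.25] # occurrence thresholds defining the blobs
  smoothing_fwhm: 3       # mm, per-subject Gaussian FWHM (sulci)
  n_perm: 1000            # permutations per test
  fdr_alpha: 0.05         # BH level for the t-test families
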