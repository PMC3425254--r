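# Default study configuration: a case-control cohort at a common gene
# deletion, with control genotype-class frequencies near 53/38/9 percent and a
# protective per-copy trend effect.
simulation:
  n_cases: 773
  n_controls: 759
  genotype_class_freqs: [0.5296, 0.3810, 0.0894]
  background_fraction: 0.095
  intensity_noise_sd: 0.10
  split_noise_sd: 0.033
  b_allele_freq: 0.5
  n_background_probes: 2000
  pop_scale: 10
  seed: 1
  disease_model:
    mode: trend
    log_or_effect: -0.3011051    # log(0.74), per additional gene copy
    intercept: -1.1
    covariate_effects: {}
modes: [cohort, reference]
association: [probe_lrr, trend, mixture]
K: 2
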