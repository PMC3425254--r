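# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Locus-only cohort (1532 samples x 5 probes) under the trend disease model.
fix_locus_cohort <- function() memo("locus_cohort", function() {
  simulate_cohort(simulation_config(n_background_probes = 0, seed = 101))
})

fix_cohort_signal <- function() memo("cohort_signal", function() {
  normalize_intensities(fix_locus_cohort()$intensities, "cohort")
})

fix_reference_signal <- function() memo("reference_signal", function() {
  co <- fix_locus_cohort()
  normalize_intensities(co$intensities, "reference",
                        reference_mask = co$truth$copy_number == 2)
})

# Locus embedded in a modest flanking background panel: calling behaviour
# must be assessed in genomic context, where entering and leaving a CNV state
# costs transitions (a bare 5-probe chromosome only pays the initial prior).
fix_flanked_cohort <- function() memo("flanked_cohort", function() {
  simulate_cohort(simulation_config(n_background_probes = 100, seed = 101))
})

fix_flanked_signals <- function() memo("flanked_signals", function() {
  co <- fix_flanked_cohort()
  list(cohort = normalize_intensities(co$intensities, "cohort"),
       reference = normalize_intensities(co$intensities, "reference",
                                         reference_mask =
                                           co$truth$copy_number == 2))
})

# Noiseless locus-only cohort for exact closed-form checks.
fix_noiseless_cohort <- function() memo("noiseless_cohort", function() {
  simulate_cohort(simulation_config(n_background_probes = 0,
                                    intensity_noise_sd = 0,
                                    split_noise_sd = 0, seed = 202))
})

# Moderate cohort with the full background panel, for QC distributions.
fix_panel_cohort <- function() memo("panel_cohort", function() {
  simulate_cohort(simulation_config(n_cases = 200, n_controls = 200,
                                    seed = 303))
})

# Two-class disease model config (carrier-vs-null odds ratio 0.66).
two_class_config <- function(seed, n_background_probes = 0) {
  simulation_config(
    disease_model = list(mode = "two_class", log_or_effect = log(0.66),
                         intercept = -1.1, covariate_effects = list()),
    n_background_probes = n_background_probes, seed = seed)
}

# Brute-force Viterbi oracle: enumerate all 5^p paths.
enumerate_best_path <- function(lrr, baf, params = hmm_params()) {
  p <- length(lrr)
  grid <- as.matrix(expand.grid(rep(list(0:4), p)))
  logp <- apply(grid, 1, function(path) {
    lp <- log(params$initial[path[1] + 1]) +
      emission_loglik(lrr[1], baf[1], path[1], params)
    if (p > 1) {
      for (j in 2:p) {
        lp <- lp + log(params$transition[path[j - 1] + 1, path[j] + 1]) +
          emission_loglik(lrr[j], baf[j], path[j], params)
      }
    }
    lp
  })
  list(best_logp = max(logp), paths = grid, logp = logp)
}

path_logprob <- function(path, lrr, baf, params = hmm_params()) {
  lp <- log(params$initial[path[1] + 1]) +
    emission_loglik(lrr[1], baf[1], path[1], params)
  for (j in seq_along(path)[-1]) {
    lp <- lp + log(params$transition[path[j - 1] + 1, path[j] + 1]) +
      emission_loglik(lrr[j], baf[j], path[j], params)
  }
  lp
}

# Rank-based AUC of a score against a binary label.
auc_score <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
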