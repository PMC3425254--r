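#' Simulation configuration for the synthetic case-control cohort
#'
#' Collects every tunable of the synthetic-data generator. Defaults encode the
#' study conditions emulated throughout the package: 773 cases and 759 controls,
#' control genotype-class frequencies of roughly 53% homozygous-null, 38%
#' heterozygous and 9% two-copy at the deletion locus, and a per-copy protective
#' trend effect on the log-odds scale.
#'
#' The intensity noise model has two components, acting on the noiseless
#' channel signals `X`, `Y` of each sample-by-probe cell:
#' \itemize{
#'   \item `intensity_noise_sd`: a shared multiplicative factor `2^e`,
#'     `e ~ N(0, intensity_noise_sd)`, applied to both channels. It moves total
#'     intensity R without moving the allelic angle theta, and equals the
#'     residual per-probe LRR noise in log2 units.
#'   \item `split_noise_sd`: an antisymmetric reallocation `+d`/`-d`,
#'     `d ~ N(0, split_noise_sd * full_signal)`, between the two channels. It
#'     moves theta (and hence BAF) without moving R; at a zero-copy sample whose
#'     residual background signal is of the same order, it spreads BAF over the
#'     whole unit interval, which is the behaviour reported for homozygously
#'     deleted samples on real arrays.
#' }
#' Negative channel values are truncated at zero (fluorescence is nonnegative).
#'
#' @param n_cases,n_controls Sample sizes of the retrospective draw.
#' @param genotype_class_freqs Probabilities of copy number 0, 1, 2 at the
#'   locus (must sum to 1).
#' @param background_fraction Fraction `f` of `full_signal` still present at
#'   zero copies. The default 0.095 solves `log2(f/(1+f)) = -3.53`, so the
#'   reference-normalized LRR of a noiseless null sample equals the 0-copy HMM
#'   state mean.
#' @param intensity_noise_sd Multiplicative total-intensity noise, log2 scale.
#' @param split_noise_sd Between-channel reallocation noise, in units of
#'   `full_signal`.
#' @param b_allele_freq Frequency of the B allele on non-deleted haplotypes.
#' @param disease_model List with elements `mode` ("trend" or "two_class"),
#'   `log_or_effect`, `intercept`, and optionally `covariate_effects` (named
#'   list of log-odds effects for `gender_male`, `age`, `smoking2`, `smoking3`).
#' @param n_background_probes Number of diploid background probes.
#' @param pop_scale Size of the simulated source population, as a multiple of
#'   `n_cases + n_controls`, from which cases and controls are drawn.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 773,
                              n_controls = 759,
                              genotype_class_freqs = c(0.5296, 0.3810, 0.0894),
                              background_fraction = 0.095,
                              intensity_noise_sd = 0.10,
                              split_noise_sd = 0.033,
                              b_allele_freq = 0.5,
                              disease_model = list(mode = "trend",
                                                   log_or_effect = log(0.74),
                                                   intercept = -1.1,
                                                   covariate_effects = list()),
                              n_background_probes = 2000,
                              pop_scale = 10,
                              seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              genotype_class_freqs = as.numeric(genotype_class_freqs),
              background_fraction = background_fraction,
              intensity_noise_sd = intensity_noise_sd,
              split_noise_sd = split_noise_sd,
              b_allele_freq = b_allele_freq,
              disease_model = disease_model,
              n_background_probes = as.integer(n_background_probes),
              pop_scale = pop_scale,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$genotype_class_freqs
  if (length(p) != 3) stop("genotype_class_freqs must have 3 entries")
  bad <- which(p < 0 | p > 1)
  if (length(bad) > 0) {
    stop("genotype_class_freqs entry ", bad[1], " (", p[bad[1]],
         ") is not a probability in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("genotype_class_freqs must sum to 1 (got ", sum(p), ")")
  }
  if (cfg$n_cases <= 0 || cfg$n_controls <= 0) {
    stop("n_cases and n_controls must be positive")
  }
  if (cfg$background_fraction < 0) stop("background_fraction must be >= 0")
  if (cfg$intensity_noise_sd < 0) stop("intensity_noise_sd must be >= 0")
  if (cfg$split_noise_sd < 0) stop("split_noise_sd must be >= 0")
  if (cfg$b_allele_freq < 0 || cfg$b_allele_freq > 1) {
    stop("b_allele_freq must be in [0, 1]")
  }
  if (!cfg$disease_model$mode %in% c("trend", "two_class")) {
    stop("unknown disease model mode: ", cfg$disease_model$mode)
  }
  invisible(cfg)
}

# Deterministic stage seeds derived from the master seed, so that stages run
# standalone reproduce the pipeline run.
derive_seed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, alleles = 202L, covariates = 303L,
               phenotype = 404L, intensities = 505L, fixture = 606L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

#' Draw locus copy-number genotypes from class frequencies
#'
#' @param n Number of samples.
#' @param class_freqs Probabilities of copy number 0, 1, 2.
#' @param seed Integer seed.
#' @return Integer vector in `{0, 1, 2}` of length `n`.
#' @export
assign_genotypes <- function(n, class_freqs, seed = 1L) {
  bad <- which(class_freqs < 0 | class_freqs > 1)
  if (length(bad) > 0) {
    stop("class_freqs entry ", bad[1], " (", class_freqs[bad[1]],
         ") is not a probability in [0, 1]")
  }
  if (abs(sum(class_freqs) - 1) > 1e-12) {
    stop("class_freqs must sum to 1 (got ", sum(class_freqs), ")")
  }
  set.seed(seed)
  sample(0:2, n, replace = TRUE, prob = class_freqs)
}

# Covariate generator. Distributions are fixture conventions for a
# hospital-based case-control study population; they carry no effect on
# disease unless covariate_effects says so.
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  gender <- ifelse(stats::runif(n) < 0.87, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, 66, 10), 21), 80)
  region <- sample(paste0("region", 1:5), n, replace = TRUE)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
  data.frame(gender = gender, age = age, region = region, smoking = smoking,
             stringsAsFactors = FALSE)
}

#' Simulate disease status under a logistic model on the locus genotype
#'
#' `logit P(case) = intercept + log_or_effect * g + covariate terms`, where `g`
#' is the copy number (mode `"trend"`) or the indicator of carrying at least
#' one gene copy (mode `"two_class"`, contrasting carriers against the
#' homozygous-null class).
#'
#' @param copy_number Integer vector of true copy numbers.
#' @param covariates Data frame from the covariate generator.
#' @param disease_model See [simulation_config()].
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` for cases.
#' @export
simulate_phenotype <- function(copy_number, covariates, disease_model,
                               seed = 1L) {
  mode <- disease_model$mode
  if (!mode %in% c("trend", "two_class")) {
    stop("unknown disease model mode: ", mode)
  }
  g <- if (mode == "trend") copy_number else as.numeric(copy_number > 0)
  eta <- disease_model$intercept + disease_model$log_or_effect * g
  ce <- disease_model$covariate_effects
  if (length(ce) > 0) {
    if (!is.null(ce$gender_male)) {
      eta <- eta + ce$gender_male * (covariates$gender == "male")
    }
    if (!is.null(ce$age)) eta <- eta + ce$age * covariates$age
    if (!is.null(ce$smoking2)) {
      eta <- eta + ce$smoking2 * (covariates$smoking == "former")
    }
    if (!is.null(ce$smoking3)) {
      eta <- eta + ce$smoking3 * (covariates$smoking == "current")
    }
  }
  set.seed(seed)
  stats::runif(length(g)) < stats::plogis(eta)
}

#' Simulate two-channel raw intensities for a cohort
#'
#' Noiseless signals follow `X = full_signal * ((c - b)/2 + f/2)` and
#' `Y = full_signal * (b/2 + f/2)` for a sample carrying `c` copies of which
#' `b` are B alleles, with `f` the residual background fraction. Noise is then
#' applied as described in [simulation_config()].
#'
#' @param copy_number Integer vector (locus copy number per sample).
#' @param b_alleles Integer matrix, samples x probes, B-allele counts. Must not
#'   exceed the number of carried copies at any cell.
#' @param probes Probe panel (see [default_probe_panel()]).
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List with nonnegative matrices `X` and `Y` (samples x probes).
#' @export
simulate_intensities <- function(copy_number, b_alleles, probes, config,
                                 seed = 1L) {
  n <- length(copy_number)
  p <- nrow(probes)
  stopifnot(nrow(b_alleles) == n, ncol(b_alleles) == p)
  cn_mat <- matrix(2L, n, p)
  cn_mat[, probes$is_locus_probe] <- copy_number
  if (any(b_alleles > cn_mat)) {
    stop("b_alleles exceeds copy number for at least one sample x probe cell")
  }
  f <- config$background_fraction
  fs <- matrix(probes$full_signal, n, p, byrow = TRUE)
  X0 <- fs * ((cn_mat - b_alleles) / 2 + f / 2)
  Y0 <- fs * (b_alleles / 2 + f / 2)
  set.seed(seed)
  gain <- 2^matrix(stats::rnorm(n * p, 0, config$intensity_noise_sd), n, p)
  split <- matrix(stats::rnorm(n * p, 0, config$split_noise_sd), n, p) * fs
  X <- pmax((X0 + split) * gain, 0)
  Y <- pmax((Y0 - split) * gain, 0)
  dimnames(X) <- dimnames(Y) <- list(NULL, probes$probe_id)
  list(X = X, Y = Y)
}

#' Simulate a complete case-control cohort with raw intensities
#'
#' Simulates a source population (genotypes, covariates, disease status under
#' the configured model), draws the requested numbers of cases and controls
#' retrospectively, and generates two-channel intensities for the drawn
#' samples. Deterministic given `config$seed`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param probes Optional probe panel; defaults to
#'   `default_probe_panel(config$n_background_probes)`.
#' @return A list of class `cnv_cohort` with elements `samples` (sample sheet
#'   data frame: `sample_id`, `status`, covariates), `truth` (`sample_id`,
#'   `copy_number`), `probes`, `intensities` (list of `X`, `Y`), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), probes = NULL) {
  validate_sim_config(config)
  if (is.null(probes)) {
    probes <- default_probe_panel(config$n_background_probes)
  }
  validate_probe_panel(probes)
  n_target <- config$n_cases + config$n_controls
  n_source <- ceiling(config$pop_scale * n_target)

  cn <- assign_genotypes(n_source, config$genotype_class_freqs,
                         derive_seed(config$seed, "genotypes"))
  covar <- simulate_covariates(n_source, derive_seed(config$seed, "covariates"))
  case <- simulate_phenotype(cn, covar, config$disease_model,
                             derive_seed(config$seed, "phenotype"))
  if (sum(case) < config$n_cases || sum(!case) < config$n_controls) {
    stop("source population too small for the requested case/control draw; ",
         "increase pop_scale (have ", sum(case), " cases, ", sum(!case),
         " controls)")
  }
  set.seed(derive_seed(config$seed, "phenotype") + 1L)
  idx <- c(sample(which(case), config$n_cases),
           sample(which(!case), config$n_controls))
  cn <- cn[idx]
  covar <- covar[idx, , drop = FALSE]
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  n <- length(idx)
  p <- nrow(probes)
  set.seed(derive_seed(config$seed, "alleles"))
  cn_mat <- matrix(2L, n, p)
  cn_mat[, probes$is_locus_probe] <- cn
  b_alleles <- matrix(stats::rbinom(n * p, as.vector(cn_mat),
                                    config$b_allele_freq), n, p)
  intens <- simulate_intensities(cn, b_alleles, probes, config,
                                 derive_seed(config$seed, "intensities"))

  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        status = status, covar, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  cohort <- list(samples = samples,
                 truth = data.frame(sample_id = samples$sample_id,
                                    copy_number = cn,
                                    stringsAsFactors = FALSE),
                 probes = probes,
                 intensities = intens,
                 config = config)
  class(cohort) <- "cnv_cohort"
  cohort
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("Synthetic CNV cohort:", nrow(x$samples), "samples (",
      sum(x$samples$status == "case"), "cases /",
      sum(x$samples$status == "control"), "controls ),",
      nrow(x$probes), "probes (", sum(x$probes$is_locus_probe),
      "at the deletion locus )\n")
  cat("True locus copy-number frequencies:\n")
  print(round(prop.table(table(factor(x$truth$copy_number, 0:2))), 4))
  invisible(x)
}

#' Simulate a summary-level LRR fixture at the compressed locus
#'
#' Generates per-probe locus LRR directly (no intensity step), with class mean
#' LRR levels as printed for the real compressed cohort-normalized data
#' (two-copy 0.17, one-copy 0.08, null -0.10 on average) and independent
#' per-probe residual noise. This is the fixture used to study concordance of
#' the latent-class mixture with truth at a realistic signal-to-noise ratio.
#'
#' @param config A `sim_config`; its sample sizes, class frequencies and
#'   disease model are reused. `intensity_noise_sd` is ignored in favour of
#'   `probe_sd`.
#' @param class_means Mean locus LRR for copy number 0, 1, 2.
#' @param probe_sd Residual per-probe LRR standard deviation.
#' @param n_probes Number of locus probes.
#' @return List with `lrr` (samples x probes matrix), `samples`, `truth`.
#' @export
simulate_lrr_fixture <- function(config = simulation_config(
                                   disease_model = list(
                                     mode = "two_class",
                                     log_or_effect = log(0.66),
                                     intercept = -1.1,
                                     covariate_effects = list())),
                                 class_means = c(-0.10, 0.08, 0.17),
                                 probe_sd = 0.10,
                                 n_probes = 5) {
  validate_sim_config(config)
  n_target <- config$n_cases + config$n_controls
  n_source <- ceiling(config$pop_scale * n_target)
  cn <- assign_genotypes(n_source, config$genotype_class_freqs,
                         derive_seed(config$seed, "genotypes"))
  covar <- simulate_covariates(n_source, derive_seed(config$seed, "covariates"))
  case <- simulate_phenotype(cn, covar, config$disease_model,
                             derive_seed(config$seed, "phenotype"))
  if (sum(case) < config$n_cases || sum(!case) < config$n_controls) {
    stop("source population too small for the requested case/control draw")
  }
  set.seed(derive_seed(config$seed, "phenotype") + 1L)
  idx <- c(sample(which(case), config$n_cases),
           sample(which(!case), config$n_controls))
  cn <- cn[idx]
  covar <- covar[idx, , drop = FALSE]
  n <- length(idx)
  set.seed(derive_seed(config$seed, "fixture"))
  lrr <- matrix(class_means[cn + 1L], n, n_probes) +
    matrix(stats::rnorm(n * n_probes, 0, probe_sd), n, n_probes)
  colnames(lrr) <- sprintf("locus_p%d", seq_len(n_probes))
  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        status = rep(c("case", "control"),
                                     c(config$n_cases, config$n_controls)),
                        covar, stringsAsFactors = FALSE)
  list(lrr = lrr,
       samples = samples,
       truth = data.frame(sample_id = samples$sample_id, copy_number = cn,
                          stringsAsFactors = FALSE))
}
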