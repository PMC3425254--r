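#' Pipeline configuration
#'
#' @param sim A `sim_config` from [simulation_config()].
#' @param modes Normalization modes to run (at least one of `"cohort"`,
#'   `"reference"`).
#' @param association Association methods to run, subset of `"probe_lrr"`,
#'   `"trend"`, `"mixture"`.
#' @param K Mixture components for the joint model.
#' @param qc A `qc_thresholds`.
#' @param hmm An `hmm_params`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            modes = c("cohort", "reference"),
                            association = c("probe_lrr", "trend", "mixture"),
                            K = 2,
                            qc = qc_thresholds(),
                            hmm = hmm_params()) {
  modes <- match.arg(modes, c("cohort", "reference"), several.ok = TRUE)
  if (length(modes) < 1) stop("at least one normalization mode required")
  structure(list(sim = sim, modes = modes, association = association, K = K,
                 qc = qc, hmm = hmm),
            class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97)) %% 4294967291)
}

#' Run the full pipeline: simulate, normalize, QC, call, associate
#'
#' Executes the whole comparison on one synthetic cohort: cohort- and/or
#' reference-mode normalization, PennCNV-style sample QC, HMM deletion calling
#' with locus deletion counts per mode, per-probe LRR regression, trend test
#' on called copies, joint mixture association, and truth-comparison metrics
#' (calling sensitivity/specificity for the null genotype, mixture-class
#' concordance). Deterministic given `config$sim$seed`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, stage outputs and
#'   `summary.tsv` are written there.
#' @param verbose Print stage log lines.
#' @return A list of class `results_bundle`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  log <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    if (verbose) message(line)
  }
  say("pipeline seed=", config$sim$seed, " config=", config_hash(config))

  cohort <- simulate_cohort(config$sim)
  n <- nrow(cohort$samples)
  say("simulate: ", n, " samples x ", nrow(cohort$probes), " probes")

  truth_cn <- cohort$truth$copy_number
  signals <- list()
  for (mode in config$modes) {
    mask <- if (mode == "reference") truth_cn == 2 else NULL
    signals[[mode]] <- normalize_intensities(cohort$intensities, mode,
                                             reference_mask = mask)
    say("normalize[", mode, "]: LRR range ",
        paste(round(range(signals[[mode]]$lrr), 2), collapse = " .. "))
  }

  qc_mode <- if ("cohort" %in% config$modes) "cohort" else config$modes[1]
  qc <- apply_qc(qc_table(signals[[qc_mode]], cohort$samples$sample_id),
                 config$qc)
  pass <- qc$pass
  say("qc[", qc_mode, "]: ", sum(pass), "/", n, " samples pass")

  locus_idx <- which(cohort$probes$is_locus_probe)
  calls <- list()
  deletion_counts <- integer(0)
  called_cn <- list()
  for (mode in config$modes) {
    sub <- signals[[mode]]
    sub$lrr <- sub$lrr[pass, , drop = FALSE]
    sub$baf <- sub$baf[pass, , drop = FALSE]
    cc <- call_cnvs(sub, cohort$probes, config$hmm,
                    cohort$samples$sample_id[pass])
    calls[[mode]] <- cc$calls
    deletion_counts[mode] <- count_locus_deletions(cc$calls, cohort$probes)
    called_cn[[mode]] <- locus_copy_number(cc$paths, cohort$probes)
    say("call[", mode, "]: ", deletion_counts[mode],
        " samples with a locus deletion call")
  }

  truth_pass <- truth_cn[pass]
  status_pass <- cohort$samples$status[pass] == "case"
  samples_pass <- cohort$samples[pass, , drop = FALSE]

  truth_metrics <- list()
  if ("reference" %in% config$modes) {
    called <- called_cn$reference
    truth_metrics$null_sensitivity <-
      mean(called[truth_pass == 0] == 0)
    truth_metrics$null_specificity <-
      mean(called[truth_pass > 0] > 0)
    say("truth[reference]: null sensitivity ",
        round(truth_metrics$null_sensitivity, 4), ", specificity ",
        round(truth_metrics$null_specificity, 4))
  }

  assoc <- list()
  if ("probe_lrr" %in% config$association) {
    lrr_locus <- signals[[qc_mode]]$lrr[pass, locus_idx, drop = FALSE]
    Xc <- covariate_design(samples_pass, age = "continuous")
    assoc$probe_lrr <- probe_lrr_tests(lrr_locus, status_pass, Xc)
  }
  if ("trend" %in% config$association) {
    trend_mode <- if ("reference" %in% config$modes) "reference" else qc_mode
    Xc <- covariate_design(samples_pass, age = "continuous")
    assoc$trend <- tryCatch(
      trend_test(called_cn[[trend_mode]], status_pass, Xc),
      error = function(e) {
        say("trend[", trend_mode, "] skipped: ", conditionMessage(e))
        NULL
      })
  }
  mixture_fit <- NULL
  if ("mixture" %in% config$association) {
    lrr_locus <- signals[[qc_mode]]$lrr[pass, locus_idx, drop = FALSE]
    s <- summarize_signal(lrr_locus, K = config$K)
    Xq <- covariate_design(samples_pass, age = "quartile")
    mixture_fit <- fit_joint_mixture(s, status_pass, Xq, K = config$K)
    assoc$mixture <- mixture_assoc_row(mixture_fit, status_pass)
    truth_metrics$concordance <-
      class_concordance(mixture_fit$classes, truth_pass == 0)
    say("mixture: OR ", round(mixture_fit$or, 3), ", concordance ",
        round(truth_metrics$concordance, 4))
  }
  association <- do.call(rbind, assoc)
  if (!is.null(association)) rownames(association) <- NULL

  bundle <- list(cohort = cohort,
                 signals = signals,
                 qc = qc,
                 calls = calls,
                 deletion_counts = deletion_counts,
                 called_copy_number = called_cn,
                 association = association,
                 mixture = mixture_fit,
                 truth_metrics = truth_metrics,
                 log = log,
                 config = config)
  class(bundle) <- "results_bundle"
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Write the results bundle to a directory
#'
#' Writes `summary.tsv` (key-value stage summary), `association_results.tsv`
#' (one row per probe plus trend/mixture rows), `qc_metrics.tsv`, per-mode
#' BED-like calls, and the run log.
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kv <- data.frame(key = character(0), value = character(0))
  add <- function(key, value) {
    kv <<- rbind(kv, data.frame(key = key, value = as.character(value)))
  }
  add("seed", bundle$config$sim$seed)
  add("config_hash", config_hash(bundle$config))
  add("n_samples", nrow(bundle$cohort$samples))
  add("n_probes", nrow(bundle$cohort$probes))
  add("qc_pass", sum(bundle$qc$pass))
  for (mode in names(bundle$deletion_counts)) {
    add(paste0("locus_deletions_", mode), bundle$deletion_counts[[mode]])
  }
  for (m in names(bundle$truth_metrics)) {
    add(m, format(bundle$truth_metrics[[m]], digits = 10))
  }
  utils::write.table(kv, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$association)) {
    utils::write.table(bundle$association,
                       file.path(dir, "association_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$qc, file.path(dir, "qc_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (mode in names(bundle$calls)) {
    write_calls_bed(bundle$calls[[mode]],
                    file.path(dir, paste0("calls_", mode, ".tsv")))
  }
  writeLines(bundle$log, file.path(dir, "log.txt"))
  invisible(bundle)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Pipeline results (seed ", x$config$sim$seed, ")\n", sep = "")
  for (mode in names(x$deletion_counts)) {
    cat(sprintf("  %s-mode locus deletion calls: %d\n", mode,
                x$deletion_counts[[mode]]))
  }
  if (!is.null(x$association)) {
    cat("  association results:\n")
    print(x$association[, c("method", "predictor", "or", "ci_low", "ci_high",
                            "p_value")], digits = 3)
  }
  invisible(x)
}
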