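#' Covariate design matrix for association models
#'
#' Expands gender, age, region and smoking into regression columns. Age enters
#' continuously for the regression tests and as four quartile classes for the
#' latent-class mixture model, which only accepts categorical adjustment.
#'
#' @param samples Sample sheet data frame with `gender`, `age`, `region`,
#'   `smoking`.
#' @param age Either `"continuous"` or `"quartile"`.
#' @return Numeric design matrix (no intercept column) with full column rank.
#' @export
covariate_design <- function(samples, age = c("continuous", "quartile")) {
  age_mode <- match.arg(age)
  df <- data.frame(
    gender = factor(samples$gender),
    region = factor(samples$region),
    smoking = factor(samples$smoking)
  )
  if (age_mode == "continuous") {
    df$age <- samples$age
  } else {
    q <- stats::quantile(samples$age, c(0.25, 0.5, 0.75))
    df$age_class <- factor(findInterval(samples$age, q))
  }
  X <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  X[, keep, drop = FALSE]
}

assoc_row <- function(method, predictor, fit, term, n_controls, n_cases,
                      covariates) {
  s <- wald_summary(fit, term)
  data.frame(method = method, predictor = predictor,
             n_controls = n_controls, n_cases = n_cases,
             coefficient = s$coefficient, se = s$se,
             or = s$or, ci_low = s$ci_low, ci_high = s$ci_high,
             p_value = s$p_value,
             covariates = covariates,
             unstable = fit$unstable,
             stringsAsFactors = FALSE)
}

#' Per-probe association of disease with locus LRR
#'
#' One covariate-adjusted logistic regression of disease status on the LRR at
#' each locus probe; the odds ratio is per unit LRR.
#'
#' @param lrr_locus Matrix of LRR at the locus probes (QC-passing samples).
#' @param phenotype Logical or 0/1 vector, `TRUE`/1 for cases.
#' @param covariates Design matrix from [covariate_design()] (or `NULL` for an
#'   unadjusted fit).
#' @return Data frame with one `AssociationResult` row per probe.
#' @export
probe_lrr_tests <- function(lrr_locus, phenotype, covariates = NULL) {
  phenotype <- as.numeric(phenotype)
  probe_ids <- colnames(lrr_locus)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%d", seq_len(ncol(lrr_locus)))
  out <- list()
  for (j in seq_len(ncol(lrr_locus))) {
    x <- lrr_locus[, j]
    if (stats::var(x) == 0) {
      stop("degenerate predictor: constant LRR at probe ", probe_ids[j])
    }
    X <- cbind(`(Intercept)` = 1, lrr = x, covariates)
    fit <- fit_logistic(phenotype, X)
    out[[j]] <- assoc_row("lrr_logistic", probe_ids[j], fit, "lrr",
                          sum(phenotype == 0), sum(phenotype == 1),
                          if (is.null(covariates)) "none" else "adjusted")
  }
  do.call(rbind, out)
}

#' Trend test: logistic regression on the number of gene copies
#'
#' Covariate-adjusted logistic fit with copy number entered as a linear
#' per-copy term; the odds ratio is per additional copy.
#'
#' @param copy_number Integer vector in 0..2 (called or true copies).
#' @param phenotype Logical or 0/1 vector.
#' @param covariates Design matrix or `NULL`.
#' @return One-row association data frame.
#' @export
trend_test <- function(copy_number, phenotype, covariates = NULL) {
  stopifnot(all(copy_number %in% 0:2))
  phenotype <- as.numeric(phenotype)
  X <- cbind(`(Intercept)` = 1, copies = as.numeric(copy_number), covariates)
  fit <- fit_logistic(phenotype, X)
  assoc_row("trend", "trend", fit, "copies",
            sum(phenotype == 0), sum(phenotype == 1),
            if (is.null(covariates)) "none" else "adjusted")
}
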