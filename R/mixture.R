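# One-dimensional Gaussian mixture by EM with component-specific variances.
# Restarts use quantile-spread means with jitter; short runs are polished to
# convergence from the best start. Components are returned sorted by mean.
gaussian_mixture_1d <- function(x, K, restarts = 10, max_iter = 500,
                                tol = 1e-8, short_iter = 15, seed = NULL) {
  n <- length(x)
  stopifnot(K >= 1, n > K)
  if (!is.null(seed)) set.seed(seed)
  sd_floor <- max(1e-4, 1e-3 * stats::sd(x))

  e_step <- function(par) {
    dens <- vapply(seq_len(K), function(k) {
      par$props[k] * stats::dnorm(x, par$means[k], par$sds[k])
    }, numeric(n))
    dens <- matrix(dens, n, K)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    list(w = dens / tot, loglik = sum(log(tot)))
  }
  m_step <- function(w) {
    nk <- colSums(w)
    nk <- pmax(nk, 1e-8)
    means <- colSums(w * x) / nk
    sds <- sqrt(colSums(w * (x - rep(means, each = n))^2) / nk)
    sds <- pmax(sds, sd_floor)
    ord <- order(means)
    list(means = means[ord], sds = sds[ord], props = (nk / n)[ord])
  }
  run <- function(par, iters, tol) {
    ll_old <- -Inf
    for (it in seq_len(iters)) {
      es <- e_step(par)
      par <- m_step(es$w)
      if (es$loglik - ll_old < tol && it > 1) break
      ll_old <- es$loglik
    }
    es <- e_step(par)
    list(par = par, loglik = es$loglik, w = es$w, iterations = it)
  }

  qs <- stats::quantile(x, (seq_len(K) - 0.5) / K, names = FALSE)
  starts <- lapply(seq_len(restarts), function(r) {
    jitter <- if (r == 1) 0 else stats::rnorm(K, 0, stats::sd(x) / 4)
    list(means = sort(qs + jitter),
         sds = rep(max(stats::sd(x) / K, sd_floor), K),
         props = rep(1 / K, K))
  })
  shorts <- lapply(starts, run, iters = short_iter, tol = 1e-4)
  best <- shorts[[which.max(vapply(shorts, `[[`, numeric(1), "loglik"))]]
  final <- run(best$par, max_iter, tol)
  list(K = K, means = final$par$means, sds = final$par$sds,
       props = final$par$props, posteriors = final$w,
       loglik = final$loglik,
       bic = -2 * final$loglik + (3 * K - 1) * log(n))
}

#' Summarize locus LRR into one signal value per sample
#'
#' Three steps: (1) first principal component of the standardized probe-LRR
#' matrix, sign-fixed to correlate positively with mean LRR; (2) provisional
#' classes from a one-dimensional K-component Gaussian mixture fitted to the
#' PC score; (3) linear discriminant direction for those classes applied to
#' the probe matrix. The discriminant score is returned (standardized probe
#' LRR itself when there is a single probe; the PC score, with a warning, when
#' the within-class covariance is singular).
#'
#' @param lrr_locus Matrix of LRR over the locus probes.
#' @param K Number of provisional classes.
#' @return Numeric vector of summary values, one per sample, with the
#'   provisional classes as attribute `"classes"`.
#' @export
summarize_signal <- function(lrr_locus, K = 2) {
  lrr_locus <- as.matrix(lrr_locus)
  n <- nrow(lrr_locus)
  if (ncol(lrr_locus) < 1) stop("at least one probe required")
  Z <- scale(lrr_locus)
  if (ncol(lrr_locus) == 1) {
    s <- drop(Z)
    attr(s, "classes") <- gaussian_mixture_1d(s, K, seed = 1)$posteriors |>
      max.col()
    return(s)
  }
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (stats::cor(score, rowMeans(lrr_locus)) < 0) score <- -score
  gm <- gaussian_mixture_1d(score, K, seed = 1)
  classes <- max.col(gm$posteriors)
  summary <- tryCatch({
    if (length(unique(classes)) < 2) stop("single provisional class")
    ld <- MASS::lda(Z, grouping = factor(classes))
    drop(Z %*% ld$scaling[, 1])
  }, error = function(e) {
    warning("discriminant step degenerate (", conditionMessage(e),
            "); falling back to the principal-component score")
    score
  })
  if (stats::cor(summary, rowMeans(lrr_locus)) < 0) summary <- -summary
  attr(summary, "classes") <- classes
  summary
}

#' Joint latent-class mixture association (CNVtools-style)
#'
#' Models the signal summary as a K-component Gaussian mixture and disease as
#' a logistic function of latent class membership: under the null, mixing
#' proportions are shared by cases and controls and disease depends only on
#' covariates; under the alternative, carrying at least one gene copy (any
#' component other than the lowest-mean, homozygous-null one) enters the
#' disease model with one log-odds parameter. Both models are fitted by EM
#' (the alternative is started from the null solution among its restarts, so
#' its log-likelihood can never fall below the null) and compared by a
#' likelihood-ratio test on one degree of freedom.
#'
#' @param summary Numeric vector from [summarize_signal()].
#' @param phenotype Logical or 0/1 disease status.
#' @param covariates Design matrix (categorical covariates recommended; age as
#'   quartile classes) or `NULL`.
#' @param K Number of mixture components.
#' @param restarts,max_iter,tol,short_iter EM controls.
#' @return A list of class `mixture_fit`: component parameters, per-sample
#'   posterior probabilities and maximum-posterior `classes` (component 1 =
#'   lowest mean = homozygous null), the carrier log-odds `coefficient` with
#'   `se`, `or`, Wald CI, the null/alternative log-likelihoods, `lrt` and
#'   `p_value`, and `bic`.
#' @export
fit_joint_mixture <- function(summary, phenotype, covariates = NULL, K = 2,
                              restarts = 30, max_iter = 500, tol = 1e-8,
                              short_iter = 15) {
  stopifnot(K >= 2)
  d <- as.numeric(phenotype)
  n <- length(summary)
  stopifnot(length(d) == n, all(d %in% 0:1))
  x <- as.numeric(summary)
  sd_floor <- max(1e-4, 1e-3 * stats::sd(x))
  Xcov <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind(`(Intercept)` = 1, as.matrix(covariates))
  }

  # Null model: plain mixture of the signal plus covariate-only disease model.
  gm0 <- gaussian_mixture_1d(x, K, restarts = restarts, max_iter = max_iter,
                             tol = tol, short_iter = short_iter, seed = 11)
  fit0 <- fit_logistic(d, Xcov)
  ll_null <- gm0$loglik + fit0$loglik

  # carrier indicator per component (component 1 after sorting = null class)
  carrier <- function(K) c(0, rep(1, K - 1))
  expand_design <- function() {
    cbind(Xcov[rep(seq_len(n), K), , drop = FALSE],
          carrier = rep(carrier(K), each = n))
  }
  Zbig <- expand_design()
  dbig <- rep(d, K)

  e_step <- function(par) {
    p_ik <- stats::plogis(drop(Xcov %*% par$gamma) +
                            outer(rep(1, n), carrier(K)) * par$beta)
    dens <- vapply(seq_len(K), function(k) {
      par$props[k] * stats::dnorm(x, par$means[k], par$sds[k]) *
        ifelse(d == 1, p_ik[, k], 1 - p_ik[, k])
    }, numeric(n))
    dens <- matrix(dens, n, K)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    list(w = dens / tot, loglik = sum(log(tot)))
  }
  m_step <- function(w, par) {
    nk <- pmax(colSums(w), 1e-8)
    means <- colSums(w * x) / nk
    sds <- pmax(sqrt(colSums(w * (x - rep(means, each = n))^2) / nk), sd_floor)
    ord <- order(means)
    w <- w[, ord, drop = FALSE]
    # weighted logistic M-step on the expanded (sample x component) rows,
    # warm-started; a few IRLS steps suffice for a generalized EM update
    coef0 <- c(par$gamma, par$beta)
    lf <- fit_logistic(dbig, Zbig, weights = as.vector(w), max_iter = 4,
                       tol = 1e-10, start = coef0)
    list(means = means[ord], sds = sds[ord],
         props = pmax(colSums(w), 1e-8)[1:K] / sum(pmax(colSums(w), 1e-8)),
         gamma = lf$coefficients[seq_len(ncol(Xcov))],
         beta = lf$coefficients[["carrier"]],
         w = w)
  }
  run <- function(par, iters, tol) {
    ll_old <- -Inf
    ll_trace <- numeric(0)
    for (it in seq_len(iters)) {
      es <- e_step(par)
      ll_trace <- c(ll_trace, es$loglik)
      ms <- m_step(es$w, par)
      par <- ms[c("means", "sds", "props", "gamma", "beta")]
      if (es$loglik - ll_old < tol && it > 1) break
      ll_old <- es$loglik
    }
    es <- e_step(par)
    list(par = par, loglik = es$loglik, w = es$w, iterations = it,
         ll_trace = ll_trace)
  }

  qs <- stats::quantile(x, (seq_len(K) - 0.5) / K, names = FALSE)
  null_start <- list(means = gm0$means, sds = gm0$sds, props = gm0$props,
                     gamma = fit0$coefficients, beta = 0)
  set.seed(13)
  starts <- c(list(null_start), lapply(seq_len(max(restarts - 1, 0)),
    function(r) {
      jitter <- if (r == 1) 0 else stats::rnorm(K, 0, stats::sd(x) / 4)
      list(means = sort(qs + jitter),
           sds = rep(max(stats::sd(x) / K, sd_floor), K),
           props = rep(1 / K, K),
           gamma = fit0$coefficients, beta = 0)
    }))
  shorts <- lapply(starts, run, iters = short_iter, tol = 1e-4)
  best <- shorts[[which.max(vapply(shorts, `[[`, numeric(1), "loglik"))]]
  final <- run(best$par, max_iter, tol)
  if (!all(diff(final$ll_trace) > -1e-6)) {
    warning("EM log-likelihood decreased beyond numerical tolerance")
  }

  # Wald se for the carrier effect at the converged posterior weights
  lf <- fit_logistic(dbig, Zbig, weights = as.vector(final$w),
                     start = c(final$par$gamma, final$par$beta))
  s <- wald_summary(lf, "carrier")
  lrt <- max(2 * (final$loglik - ll_null), 0)
  out <- list(K = K,
              means = final$par$means, sds = final$par$sds,
              props = final$par$props,
              posteriors = final$w,
              classes = max.col(final$w),
              coefficient = final$par$beta,
              se = s$se, or = exp(final$par$beta),
              ci_low = exp(final$par$beta - 1.959964 * s$se),
              ci_high = exp(final$par$beta + 1.959964 * s$se),
              loglik_null = ll_null, loglik_alt = final$loglik,
              lrt = lrt,
              p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
              bic = -2 * final$loglik +
                (3 * K - 1 + ncol(Xcov) + 1) * log(n),
              iterations = final$iterations,
              ll_trace = final$ll_trace)
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Joint latent-class mixture association (K =", x$K, ")\n")
  cat("component means:", paste(round(x$means, 3), collapse = ", "),
      "| mixing:", paste(round(x$props, 3), collapse = ", "), "\n")
  cat(sprintf("carrier vs null OR = %.3f [%.3f-%.3f], LRT p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Concordance between mixture classes and true null status
#'
#' Fraction of samples whose maximum-posterior component (component 1, the
#' lowest-mean one, interpreted as homozygous null) matches the true null
#' status.
#'
#' @param classes Integer vector of maximum-posterior component labels.
#' @param truth_null Logical vector, `TRUE` for true copy number 0.
#' @return Fraction in `[0, 1]`.
#' @export
class_concordance <- function(classes, truth_null) {
  stopifnot(length(classes) == length(truth_null))
  mean((classes == 1) == as.logical(truth_null))
}

#' Mixture association row for the results table
#'
#' @param fit A `mixture_fit`.
#' @param phenotype Logical or 0/1 disease status.
#' @return One-row association data frame matching [trend_test()] output.
#' @export
mixture_assoc_row <- function(fit, phenotype) {
  phenotype <- as.numeric(phenotype)
  data.frame(method = "mixture", predictor = "mixture",
             n_controls = sum(phenotype == 0), n_cases = sum(phenotype == 1),
             coefficient = fit$coefficient, se = fit$se,
             or = fit$or, ci_low = fit$ci_low, ci_high = fit$ci_high,
             p_value = fit$p_value, covariates = "adjusted",
             unstable = FALSE, stringsAsFactors = FALSE)
}
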