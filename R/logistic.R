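#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors; supports
#' fractional case weights, which the joint mixture model uses for its
#' weighted M-step. Convergence when the largest coefficient change falls
#' below `tol` or after `max_iter` iterations. Fits with any
#' `|coefficient| > 15` are flagged unstable (quasi-separation).
#'
#' @param y Binary outcome (0/1 or logical).
#' @param X Design matrix including the intercept column; must be full rank.
#' @param weights Optional nonnegative observation weights.
#' @param offset Optional linear-predictor offset.
#' @param max_iter,tol IRLS controls.
#' @param start Optional starting coefficients.
#' @return List with `coefficients`, `se`, `vcov`, `loglik`, `fitted`,
#'   `p_values` (Wald), `converged`, `unstable`, `iterations`.
#' @export
fit_logistic <- function(y, X, weights = NULL, offset = NULL,
                         max_iter = 50, tol = 1e-8, start = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0 & y <= 1))
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(offset)) offset <- rep(0, n)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not of full column rank")
  k <- ncol(X)
  beta <- if (is.null(start)) rep(0, k) else start
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- stats::plogis(eta)
    w <- weights * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta - offset + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    delta <- drop(fit) - beta
    beta <- drop(fit)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta) + offset
  mu <- stats::plogis(eta)
  info <- t(X * (weights * mu * (1 - mu))) %*% X
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(vcov), 0))
  loglik <- sum(weights * (y * log(pmax(mu, 1e-300)) +
                             (1 - y) * log(pmax(1 - mu, 1e-300))))
  zstat <- beta / se
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       vcov = vcov,
       loglik = loglik,
       fitted = mu,
       p_values = stats::setNames(2 * stats::pnorm(-abs(zstat)), colnames(X)),
       converged = converged,
       unstable = any(abs(beta) > 15),
       iterations = iter)
}

# Wald 95% CI and OR summary for one coefficient of a fitted logistic model.
wald_summary <- function(fit, term) {
  b <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  list(coefficient = b, se = se, or = exp(b),
       ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
       p_value = fit$p_values[[term]])
}
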