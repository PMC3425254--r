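test_that("per-probe LRR regression finds the protective direction at every probe", {
  co <- fix_locus_cohort()
  res <- probe_lrr_tests(fix_cohort_signal()$lrr,
                         co$samples$status == "case",
                         covariate_design(co$samples, "continuous"))
  expect_equal(nrow(res), 5)
  expect_true(all(res$or < 1))
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_error(probe_lrr_tests(matrix(1, 100, 1),
                               rep(0:1, 50)), "degenerate predictor")
})

test_that("trend estimates on called copies track those on true copies", {
  co <- fix_locus_cohort()
  called <- locus_copy_number(call_cnvs(fix_reference_signal(),
                                        co$probes)$paths, co$probes)
  Xc <- covariate_design(co$samples, "continuous")
  d <- co$samples$status == "case"
  or_called <- trend_test(called, d, Xc)$or
  or_true <- trend_test(co$truth$copy_number, d, Xc)$or
  expect_lt(abs(or_called - or_true), 0.03)
  # single-fixture estimate lands near the generating per-copy effect
  expect_lt(abs(or_true - 0.74), 0.15)
})

test_that("trend test recovers a null effect", {
  set.seed(3)
  cn <- assign_genotypes(2000, c(0.5296, 0.3810, 0.0894), seed = 3)
  d <- rbinom(2000, 1, 0.5)
  expect_lt(abs(trend_test(cn, d)$or - 1), 0.15)
})

test_that("the signal summary degenerates gracefully and separates classes", {
  co <- fix_locus_cohort()
  lrr <- fix_cohort_signal()$lrr
  # single probe: summary equals the standardized LRR of that probe
  s1 <- summarize_signal(lrr[, 1, drop = FALSE])
  expect_equal(as.vector(s1), as.vector(scale(lrr[, 1])))
  # full locus: the discriminant score separates null from carrier
  s <- summarize_signal(lrr, K = 2)
  expect_gt(auc_score(s, co$truth$copy_number > 0), 0.95)
})

test_that("the discriminant direction maximizes the between/within ratio", {
  set.seed(41)
  n <- 300
  cls <- rbinom(n, 1, 0.5)
  x <- cbind(rnorm(n, 3 * cls, 1), rnorm(n, -2 * cls, 1))
  Z <- scale(x)
  s <- summarize_signal(Z, K = 2)
  # oracle: grid search over directions for the Fisher between/within ratio,
  # using the same provisional classes the summary used
  prov <- attr(s, "classes")
  expect_equal(length(unique(prov)), 2L)
  ratio <- function(ang) {
    v <- c(cos(ang), sin(ang))
    p <- drop(Z %*% v)
    m <- tapply(p, prov, mean)
    b <- diff(m)^2
    w <- sum(tapply(p, prov, function(z) sum((z - mean(z))^2))) / (n - 2)
    b / w
  }
  angles <- seq(0, pi, length.out = 40001)
  best <- angles[which.max(vapply(angles, ratio, numeric(1)))]
  # recover the direction the summary actually used (s = Z v exactly)
  v <- qr.solve(Z, matrix(s))
  got <- atan2(v[2], v[1]) %% pi
  expect_lt(min(abs(got - best), pi - abs(got - best)), 1e-3)
})

test_that("1-d mixture EM matches a coarse grid oracle on a toy sample", {
  set.seed(29)
  x <- c(rnorm(10, -1, 0.4), rnorm(10, 1.5, 0.4))
  gm <- cnvlrr:::gaussian_mixture_1d(x, K = 2, restarts = 10)
  grid <- expand.grid(m1 = seq(-2, 0.5, 0.05), m2 = seq(0.5, 2.5, 0.05),
                      s = seq(0.2, 1, 0.05), p = seq(0.2, 0.8, 0.1))
  ll <- mapply(function(m1, m2, s, p) {
    sum(log(p * dnorm(x, m1, s) + (1 - p) * dnorm(x, m2, s)))
  }, grid$m1, grid$m2, grid$s, grid$p)
  expect_gte(gm$loglik, max(ll) - 1e-3)
  expect_true(all(diff(gm$means) > 0))
  expect_equal(rowSums(gm$posteriors), rep(1, 20), tolerance = 1e-8)
})

test_that("1-d mixture EM agrees with an independent EM implementation", {
  withr::local_package("mclust")
  set.seed(37)
  x <- c(rnorm(120, -0.5, 0.3), rnorm(80, 1, 0.5))
  gm <- cnvlrr:::gaussian_mixture_1d(x, K = 2, restarts = 10)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # same optimum up to each implementation's convergence slack, and ours is
  # never the worse of the two
  expect_lt(abs(gm$loglik - mc$loglik), 0.05)
  expect_gte(gm$loglik, mc$loglik - 1e-3)
  expect_equal(sort(gm$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("joint mixture association is calibrated under independence", {
  set.seed(53)
  fx <- simulate_lrr_fixture(simulation_config(
    disease_model = list(mode = "two_class", log_or_effect = 0,
                         intercept = -1.1, covariate_effects = list()),
    n_cases = 400, n_controls = 400, n_background_probes = 0, seed = 61))
  s <- summarize_signal(fx$lrr, K = 2)
  fit <- fit_joint_mixture(s, fx$samples$status == "case",
                           covariate_design(fx$samples, "quartile"), K = 2)
  expect_lt(abs(log(fit$or)), 0.35)
  expect_gt(fit$p_value, 0.001)
  expect_gte(fit$loglik_alt, fit$loglik_null - 1e-6)
  expect_gte(fit$lrt, 0)
  expect_equal(rowSums(fit$posteriors), rep(1, 800), tolerance = 1e-8)
  expect_true(all(diff(fit$means) > 0))
  expect_true(all(diff(fit$ll_trace) > -1e-6))
})

test_that("joint mixture recovers the two-class effect from intensities", {
  co <- simulate_cohort(two_class_config(71))
  sig <- normalize_intensities(co$intensities, "cohort")
  s <- summarize_signal(sig$lrr, K = 2)
  fit <- fit_joint_mixture(s, co$samples$status == "case",
                           covariate_design(co$samples, "quartile"), K = 2)
  expect_lt(abs(fit$or - 0.66), 0.12)
  expect_lt(fit$p_value, 0.05)
  # component 1 is the homozygous-null class
  expect_gt(class_concordance(fit$classes, co$truth$copy_number == 0), 0.95)
})

test_that("concordance is exact for perfect labels and near chance for shuffled ones", {
  truth <- c(rep(TRUE, 530), rep(FALSE, 470))
  classes <- ifelse(truth, 1, 2)
  expect_equal(class_concordance(classes, truth), 1.0)
  set.seed(97)
  shuffled <- sample(classes)
  expect_lt(abs(class_concordance(shuffled, truth) - 0.5), 0.06)
})

test_that("all three methods agree on the effect direction across seeds", {
  for (seed in 1:8) {
    co <- simulate_cohort(simulation_config(n_background_probes = 0,
                                            seed = 400 + seed))
    sig <- normalize_intensities(co$intensities, "cohort")
    d <- co$samples$status == "case"
    Xc <- covariate_design(co$samples, "continuous")
    probe_or <- probe_lrr_tests(sig$lrr, d, Xc)$or
    trend_or <- trend_test(co$truth$copy_number, d, Xc)$or
    s <- summarize_signal(sig$lrr, K = 2)
    mix_or <- fit_joint_mixture(s, d, covariate_design(co$samples, "quartile"),
                                K = 2)$or
    expect_true(all(probe_or < 1))
    expect_lt(trend_or, 1)
    expect_lt(mix_or, 1)
  }
})
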