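test_that("genotype assignment validates inputs and names the offender", {
  expect_error(assign_genotypes(10, c(0.5, 0.6, -0.1)), "entry 3")
  expect_error(assign_genotypes(10, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_identical(assign_genotypes(50, c(0, 0, 1)), rep(2L, 50) + 0L)
})

test_that("genotype frequencies converge to the configured classes", {
  freqs <- c(0.5296, 0.3810, 0.0894)
  g <- assign_genotypes(100000, freqs, seed = 7)
  obs <- tabulate(g + 1, 3)
  gof <- suppressWarnings(stats::chisq.test(obs, p = freqs))
  expect_gt(gof$p.value, 0.001)

  g <- assign_genotypes(759, freqs, seed = 7)
  for (k in 0:2) {
    se <- sqrt(freqs[k + 1] * (1 - freqs[k + 1]) / 759)
    expect_lt(abs(mean(g == k) - freqs[k + 1]), 3 * se)
  }
})

test_that("noiseless intensities follow the stated channel formulas", {
  probes <- default_probe_panel(0)[1, , drop = FALSE]
  cfg0 <- simulation_config(intensity_noise_sd = 0, split_noise_sd = 0,
                            background_fraction = 0)
  # symmetric heterozygote, f = 0
  i <- simulate_intensities(2L, matrix(1L), probes, cfg0)
  expect_equal(unname(i$X[1, 1]), 0.5)
  expect_equal(unname(i$Y[1, 1]), 0.5)
  # homozygous null with residual background f = 0.095
  cfgf <- simulation_config(intensity_noise_sd = 0, split_noise_sd = 0)
  i <- simulate_intensities(0L, matrix(0L), probes, cfgf)
  expect_equal(unname(i$X[1, 1]), 0.0475)
  expect_equal(unname(i$Y[1, 1]), 0.0475)
  expect_equal(unname(i$X[1, 1] + i$Y[1, 1]), 0.095)
  # one copy, A allele: R = 0.595, reference LRR ~ -0.88 near the 1-copy mean
  i <- simulate_intensities(1L, matrix(0L), probes, cfgf)
  R <- unname(i$X[1, 1] + i$Y[1, 1])
  expect_equal(R, 0.595)
  lrr <- log2(R / 1.095)
  expect_equal(round(lrr, 2), -0.88)
  means <- c(-3.53, -0.66, 0, 0.40, 0.68)
  expect_equal(which.min(abs(lrr - means)), 2L)  # one-copy state

  expect_error(simulate_intensities(1L, matrix(2L), probes, cfgf),
               "exceeds copy number")
})

test_that("noiseless total intensity is strictly increasing in copy number", {
  probes <- default_probe_panel(0)
  cfg <- simulation_config(intensity_noise_sd = 0, split_noise_sd = 0)
  R <- sapply(0:2, function(c) {
    i <- simulate_intensities(rep(c, 4), matrix(0L, 4, 5), probes, cfg)
    mean(i$X + i$Y)
  })
  expect_true(all(diff(R) > 0))
})

test_that("the default cohort has the published sample and probe counts", {
  co <- simulate_cohort(simulation_config(seed = 5))
  expect_equal(nrow(co$samples), 1532)
  expect_equal(sum(co$samples$status == "case"), 773)
  expect_equal(sum(co$samples$status == "control"), 759)
  expect_equal(nrow(co$probes), 2005)
  expect_equal(sum(co$probes$is_locus_probe), 5)
  # locus probes at the published coordinates, sorted
  loc <- co$probes[co$probes$is_locus_probe, ]
  expect_equal(loc$position,
               c(110032359L, 110034047L, 110034670L, 110034988L, 110035809L))
})

test_that("cohort simulation is deterministic in the seed", {
  a <- simulate_cohort(simulation_config(n_background_probes = 10, seed = 42))
  b <- simulate_cohort(simulation_config(n_background_probes = 10, seed = 42))
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(simulation_config(n_background_probes = 10, seed = 43))
  expect_false(identical(a$truth$copy_number, c$truth$copy_number))
})

test_that("phenotype simulation reproduces the generating odds ratios", {
  n <- 100000
  cn <- assign_genotypes(n, c(0.5296, 0.3810, 0.0894), seed = 11)
  covar <- simulate_covariates(n, seed = 11)
  # null effect: empirical OR ~ 1
  d0 <- simulate_phenotype(cn, covar, list(mode = "trend", log_or_effect = 0,
                                           intercept = -1, covariate_effects = list()),
                           seed = 1)
  or0 <- exp(coef(glm(d0 ~ cn, family = binomial()))[["cn"]])
  expect_lt(abs(or0 - 1), 0.05)
  # trend effect ln(0.74): independent check with glm
  dt <- simulate_phenotype(cn, covar, list(mode = "trend",
                                           log_or_effect = log(0.74),
                                           intercept = -1,
                                           covariate_effects = list()),
                           seed = 2)
  ort <- exp(coef(glm(dt ~ cn, family = binomial()))[["cn"]])
  expect_lt(abs(ort - 0.74), 0.03)
  # two-class effect ln(0.66): brute-force contingency cross-product,
  # null-vs-carrier orientation gives 1/0.66
  d2 <- simulate_phenotype(cn, covar, list(mode = "two_class",
                                           log_or_effect = log(0.66),
                                           intercept = -1,
                                           covariate_effects = list()),
                           seed = 3)
  tab <- table(null = cn == 0, case = d2)
  or2 <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  expect_lt(abs(or2 - 1 / 0.66), 0.08)
  expect_error(simulate_phenotype(cn, covar, list(mode = "bogus",
                                                  log_or_effect = 0,
                                                  intercept = 0)),
               "unknown disease model mode")
})

test_that("null phenotype simulation gives uniform association p-values", {
  n <- 600
  cn <- assign_genotypes(n, c(0.5296, 0.3810, 0.0894), seed = 21)
  covar <- simulate_covariates(n, seed = 21)
  pvals <- vapply(1:200, function(s) {
    d <- simulate_phenotype(cn, covar,
                            list(mode = "trend", log_or_effect = 0,
                                 intercept = 0, covariate_effects = list()),
                            seed = s)
    suppressWarnings(stats::chisq.test(table(cn, d))$p.value)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("retrospective sampling fixes the case/control margins", {
  co <- fix_locus_cohort()
  expect_equal(table(co$samples$status)[["case"]], 773)
  expect_equal(table(co$samples$status)[["control"]], 759)
  expect_true(all(co$truth$copy_number %in% 0:2))
  expect_error(simulation_config(n_cases = 0), "positive")
})
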