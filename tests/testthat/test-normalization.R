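test_that("polar transform matches closed-form values", {
  p <- compute_polar(matrix(c(2, 0, 1)), matrix(c(0, 2, 3)))
  expect_equal(p$theta[, 1], c(0, 1, (2 / pi) * atan(3)))
  expect_equal(p$R[, 1], c(2, 2, 4))
  expect_equal(round(p$theta[3, 1], 4), 0.7952)
  # both channels zero -> theta defined as 0.5
  expect_equal(compute_polar(matrix(0), matrix(0))$theta[1, 1], 0.5)
  expect_error(compute_polar(matrix(-1), matrix(1)), "nonnegative")
  expect_error(compute_polar(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("homogeneous diploid cohort yields full-signal clusters in both modes", {
  cfg <- simulation_config(genotype_class_freqs = c(0, 0, 1),
                           intensity_noise_sd = 0, split_noise_sd = 0,
                           n_cases = 150, n_controls = 150,
                           n_background_probes = 0, seed = 7)
  co <- simulate_cohort(cfg)
  polar <- compute_polar(co$intensities$X, co$intensities$Y)
  mc <- fit_cluster_model(polar$theta, polar$R, "cohort")
  expect_equal(sort(unique(mc$cluster)), c("AA", "AB", "BB"))
  expect_equal(mc$r_expected, rep(1.095, nrow(mc)), tolerance = 1e-12)
  # reference mask covering everyone makes the two modes coincide
  mr <- fit_cluster_model(polar$theta, polar$R, "reference",
                          reference_mask = rep(TRUE, 300))
  expect_equal(mc$r_expected, mr$r_expected)
  expect_equal(mc$theta_center, mr$theta_center)
  expect_error(fit_cluster_model(polar$theta, polar$R, "reference"),
               "reference_mask")
})

test_that("cohort-mode cluster expectations are depressed at the locus", {
  co <- fix_locus_cohort()
  polar <- compute_polar(co$intensities$X, co$intensities$Y)
  mc <- fit_cluster_model(polar$theta, polar$R, "cohort")
  mr <- fit_cluster_model(polar$theta, polar$R, "reference",
                          reference_mask = co$truth$copy_number == 2)
  merged <- merge(mc, mr, by = c("probe_id", "cluster"))
  expect_gt(nrow(merged), 0)
  expect_true(all(merged$r_expected.x < merged$r_expected.y))
})

test_that("LRR definition: observed equal to expected gives zero", {
  theta <- matrix(c(0.1, 0.5, 0.9), 3, 1, dimnames = list(NULL, "p1"))
  R <- matrix(1.095, 3, 1, dimnames = list(NULL, "p1"))
  model <- fit_cluster_model(theta, R, "cohort", min_cluster_size = 1)
  sig <- compute_lrr_baf(theta, R, model)
  expect_equal(sig$lrr, matrix(0, 3, 1, dimnames = list(NULL, "p1")))
})

test_that("noiseless reference-mode null LRR equals the 0-copy state mean", {
  co <- fix_noiseless_cohort()
  sig <- normalize_intensities(co$intensities, "reference",
                               reference_mask = co$truth$copy_number == 2)
  null_lrr <- sig$lrr[co$truth$copy_number == 0, ]
  expect_equal(unname(round(unique(as.vector(null_lrr)), 3)), -3.527)
  expect_equal(log2(0.095 / 1.095), -3.5268, tolerance = 1e-4)
  # reference mode: strictly increasing in copy number at every probe
  m <- sapply(0:2, function(c) {
    colMeans(sig$lrr[co$truth$copy_number == c, , drop = FALSE])
  })
  expect_true(all(m[, 1] < m[, 2] & m[, 2] < m[, 3]))
  # cohort mode: non-decreasing; compression zeroes the deleted classes but
  # cannot invert the ordering
  cohort_sig <- normalize_intensities(co$intensities, "cohort")
  mc <- sapply(0:2, function(c) {
    colMeans(cohort_sig$lrr[co$truth$copy_number == c, , drop = FALSE])
  })
  expect_true(all(mc[, 1] <= mc[, 2] + 1e-9 & mc[, 2] < mc[, 3]))
})

test_that("theta and BAF stay inside the unit interval", {
  for (sig in list(fix_cohort_signal(), fix_reference_signal())) {
    expect_true(all(sig$theta >= 0 & sig$theta <= 1))
    expect_true(all(sig$baf >= 0 & sig$baf <= 1))
    expect_true(all(is.finite(sig$lrr)))
  }
})

test_that("cohort normalization compresses null LRR while reference exposes it", {
  co <- fix_locus_cohort()
  null <- co$truth$copy_number == 0
  cohort_null <- fix_cohort_signal()$lrr[null, ]
  ref_null <- fix_reference_signal()$lrr[null, ]
  # compression: null samples look diploid under cohort normalization
  expect_true(all(cohort_null > -1 & cohort_null < 1))
  expect_lt(max(colMeans(ref_null)), -2.5)
  # class ordering survives compression
  m <- sapply(0:2, function(c) {
    colMeans(fix_cohort_signal()$lrr[co$truth$copy_number == c, , drop = FALSE])
  })
  expect_true(all(m[, 1] < m[, 2] & m[, 2] < m[, 3]))
  expect_lt(max(abs(m[, 1])), 0.25)  # null class mean LRR near zero
})

test_that("null-sample BAF spreads across the unit interval under cohort mode", {
  co <- fix_locus_cohort()
  b <- as.vector(fix_cohort_signal()$baf[co$truth$copy_number == 0, ])
  # wide dispersion, far from the tight canonical bands of diploid samples
  expect_gt(mean(b > 0.25 & b < 0.75), 0.25)
  expect_gt(mean(b < 0.25), 0.1)
  expect_gt(mean(b > 0.75), 0.1)
})

test_that("zero-intensity cells are floored and flagged", {
  theta <- matrix(c(0.1, 0.5, 0.9, 0.5), 4, 1, dimnames = list(NULL, "p1"))
  R <- matrix(c(1, 1, 1, 0), 4, 1, dimnames = list(NULL, "p1"))
  model <- fit_cluster_model(theta, R, "cohort", min_cluster_size = 1)
  sig <- compute_lrr_baf(theta, R, model)
  expect_equal(unname(sig$lrr[4, 1]), -10)
  expect_true(sig$dropout[4, 1])
  expect_false(any(sig$dropout[1:3, 1]))
})
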