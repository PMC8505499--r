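test_that("single-component sampling matches the Gaussian limit", {
  p <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5), c(1, 60, 8, 0))
  v <- sample_voxels(p, 2e5, seed = 1)
  expect_equal(mean(v), 60, tolerance = 0.1)
  expect_equal(sd(v), 8, tolerance = 0.1)
})

test_that("voxel sampling is seed-reproducible and rejects empty models", {
  p <- ref_params()
  expect_identical(sample_voxels(p, 1000, seed = 5),
                   sample_voxels(p, 1000, seed = 5))
  expect_false(identical(sample_voxels(p, 1000, seed = 5),
                         sample_voxels(p, 1000, seed = 6)))
  v <- sample_voxels(p, 5000, seed = 2)
  expect_true(all(v >= -200 & v < 200))
  p0 <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5), c(0, 60, 5, 0))
  expect_error(sample_voxels(p0, 10), "amplitudes")
})

test_that("sampled histograms round-trip through the fit", {
  p <- ref_params()
  h <- bin_voxels(sample_voxels(p, 1e5, seed = 77))
  fit <- ntra_fit(h, scale = ref_total_mass(), seed = 77)
  rel <- abs(coef(fit) - as.numeric(p)) / abs(as.numeric(p))
  expect_lt(median(rel), 0.05)
})

test_that("default cohorts reproduce the configured marginals", {
  gen <- generate_cohort(cohort_config(n_subjects = 3000, seed = 8))
  d <- gen$cohort
  probs <- cohort_reference_marginals()$pa_probs
  freq <- tabulate(d$pa, 5) / nrow(d)
  # binomial sampling error: 4 SEs per category
  tol <- 4 * sqrt(probs * (1 - probs) / nrow(d))
  expect_true(all(abs(freq - probs) < tol))
  expect_equal(mean(d$age), 74.9, tolerance = 0.5)
  expect_equal(mean(d$bmi), 27.3, tolerance = 0.5)
  expect_equal(mean(d$sex == 0), 0.58, tolerance = 0.05)  # 0 = female
  expect_equal(mean(d$muscle_N),
               cohort_reference_marginals()$ntra_followup$mean[["muscle_N"]],
               tolerance = 1.5)
})

test_that("cohort generation is deterministic and validates its config", {
  cfg <- muscle_mediation_scenario(200, seed = 13)
  expect_identical(generate_cohort(cfg)$cohort, generate_cohort(cfg)$cohort)
  mg <- cohort_reference_marginals()
  mg$pa_probs <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(cohort_config(marginals = mg), "sum to 1")
})

test_that("planted ground truth is additive and carried in the output", {
  gen <- generate_cohort(muscle_mediation_scenario(100, seed = 1))
  for (t in names(gen$truth)) {
    tr <- gen$truth[[t]]
    expect_equal(tr$total_indirect, sum(tr$specific_indirect),
                 tolerance = 1e-12)
  }
  # timed up-and-go paths are sign-flipped (higher = worse)
  expect_lt(gen$truth$tug$direct, 0)
  expect_lt(gen$truth$tug$total_indirect, 0)
  expect_gt(gen$truth$gsf$total_indirect, 0)
})

test_that("standardized planted paths are recovered at large n", {
  # a = 0.3, b = 0.5 on the standardized scale: the product of the
  # standardized regression estimates converges to 0.15
  cfg <- bare_config(20000, a_val = 0.3, b_val = 0.5, seed = 21)
  gen <- generate_cohort(cfg)
  a_hat <- fit_ols(muscle_N ~ pa + age + sex + bmi, gen$cohort)
  b_hat <- fit_ols(gsf_fu ~ pa + muscle_N + age + sex + bmi + gsf_base,
                   gen$cohort)
  a_std <- ols_coef(a_hat, "pa", "beta")
  b_std <- ols_coef(b_hat, "muscle_N", "beta")
  expect_equal(a_std * b_std, 0.15, tolerance = 0.02)
})
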