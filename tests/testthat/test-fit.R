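test_that("moment-based initialization respects the tissue domains", {
  # a pure Gaussian confined to the muscle domain
  v <- withr::with_seed(3, rnorm(5e4, 70, 6))
  h <- bin_voxels(v)
  init <- ntra_init(h)
  expect_lt(abs(init[["muscle_mu"]] - mean(v)), 0.5)
  expect_equal(init[["fat_N"]], 0)
  expect_equal(init[["conn_N"]], 0)
  # degenerate fat domain falls back to the stated midpoint rule
  expect_equal(init[["fat_mu"]], -105)
  expect_equal(init[["fat_sigma"]], 190 / 6, tolerance = 1e-8)

  # realistic trimodal sample: starts land inside their canonical domains
  h2 <- bin_voxels(sample_voxels(ref_params(), 5e4, seed = 4))
  i2 <- ntra_init(h2)
  expect_true(i2[["fat_mu"]] >= -200 && i2[["fat_mu"]] <= -10)
  expect_true(i2[["conn_mu"]] >= -9.5 && i2[["conn_mu"]] <= 40.5)
  expect_true(i2[["muscle_mu"]] >= 40.5 && i2[["muscle_mu"]] <= 200)
})

test_that("fitting a noise-free tabulated curve recovers the parameters", {
  p <- ref_params()
  mids <- seq(-200, 200 - 1, by = 1) + 0.5
  counts <- trimodal_density(mids, p)
  h <- hu_histogram(counts)
  fit <- ntra_fit(h, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  est <- coef(fit)
  tru <- as.numeric(p)
  mus <- c("fat_mu", "conn_mu", "muscle_mu")
  expect_true(all(abs(est[mus] - tru[match(mus, names(est))]) < 0.2))
  others <- setdiff(names(est), mus)
  rel <- abs(est[others] - tru[match(others, names(est))]) /
    abs(tru[match(others, names(est))])
  expect_true(all(rel < 0.01))
  expect_gt(fit$r_squared, 0.999)
})

test_that("sampled voxels from known parameters are recovered", {
  # per-seed, locations land within 1 HU; across seeds the per-parameter
  # median relative error stays below 5% (the skewness estimates carry the
  # largest sampling noise under least squares on bin heights)
  p <- ref_params()
  tru <- as.numeric(p)
  mus <- c("fat_mu", "conn_mu", "muscle_mu")
  rel_all <- NULL
  for (s in c(101, 202, 303)) {
    h <- bin_voxels(sample_voxels(p, 1e5, seed = s))
    fit <- ntra_fit(h, scale = ref_total_mass(), seed = s)
    est <- coef(fit)
    expect_true(all(abs(est[mus] - tru[match(mus, names(est))]) < 1),
                label = paste("locations at seed", s))
    expect_gt(fit$r_squared, 0.95)
    rel_all <- rbind(rel_all, abs(est - tru) / abs(tru))
  }
  expect_true(all(apply(rel_all, 2, median) < 0.05))
})

test_that("refitting from a recovered optimum is idempotent", {
  h <- bin_voxels(sample_voxels(ref_params(), 5e4, seed = 8))
  fit <- ntra_fit(h, seed = 8)
  refit <- ntra_fit(h, init = fit$params, n_starts = 1)
  expect_lt(abs(refit$objective - fit$objective),
            1e-8 * max(fit$objective, 1e-12))
})

test_that("a single-bin histogram produces a flagged degenerate fit", {
  counts <- rep(0, 400)
  counts[260] <- 1000
  h <- hu_histogram(counts)
  fit <- ntra_fit(h, n_starts = 2, seed = 1)
  expect_true(fit$degenerate)
  expect_true(any(grepl("sigma", fit$at_bounds)))
})

test_that("goodness of fit behaves at its boundaries", {
  p <- ref_params()
  mids <- seq(-200, 199, by = 1) + 0.5
  h <- hu_histogram(trimodal_density(mids, p))
  g <- ntra_gof(h, p)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
  expect_equal(g$rmse, 0, tolerance = 1e-12)

  # an all-zero model against a nonconstant histogram cannot beat the mean
  p0 <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5), c(0, 60, 5, 0))
  expect_lte(ntra_gof(h, p0)$r_squared, 0)

  # zero-variance histogram: r-squared undefined
  flat <- hu_histogram(rep(3, 400))
  expect_true(is.na(ntra_gof(flat, p)$r_squared))
})

test_that("fit surface errors and methods are coherent", {
  expect_error(ntra_fit(hu_histogram(rep(0, 400))), "zero total")
  h <- bin_voxels(sample_voxels(ref_params(), 3e4, seed = 12))
  fit <- ntra_fit(h, seed = 12, n_starts = 2)
  expect_s3_class(fit, "ntra_fit")
  expect_length(coef(fit), 11)
  expect_length(residuals(fit), length(h$counts))
  expect_equal(fitted(fit) + residuals(fit), fit$heights)
  expect_equal(predict(fit, newdata = 0),
               trimodal_density(0, fit$params))
  sim <- simulate(fit, nsim = 100, seed = 1)
  expect_length(sim, 100)
  expect_identical(sim, simulate(fit, nsim = 100, seed = 1))
})
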