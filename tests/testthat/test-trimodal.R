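test_that("component density has the closed-form apex for any skewness", {
  expect_equal(component_density(0, N = 1, mu = 0, sigma = 1, alpha = 0),
               1 / sqrt(2 * pi))
  # erfc(0) = 1, so the apex is N / (sigma * sqrt(2*pi)) regardless of alpha
  expect_equal(component_density(61.5, N = 78, mu = 61.5, sigma = 8.6,
                                 alpha = 2.8),
               78 / (8.6 * sqrt(2 * pi)))
  withr::with_seed(11, {
    for (i in 1:25) {
      N <- runif(1, 0.1, 100); mu <- runif(1, -150, 150)
      sigma <- runif(1, 0.6, 40); alpha <- runif(1, -8, 8)
      expect_equal(component_density(mu, N, mu, sigma, alpha),
                   N / (sigma * sqrt(2 * pi)))
    }
  })
})

test_that("zero skewness gives a symmetric curve, and density is never negative", {
  d <- seq(0.5, 30, by = 0.5)
  expect_equal(component_density(10 + d, 5, 10, 4, 0),
               component_density(10 - d, 5, 10, 4, 0))
  x <- seq(-200, 200, by = 0.25)
  vals <- component_density(x, 62, -117.8, 8.2, -2.5)
  expect_true(all(vals >= 0))
})

test_that("invalid component parameters are rejected", {
  expect_error(component_density(0, 1, 0, -1, 0), "sigma")
  expect_error(component_density(0, 1, 0, 0, 0), "sigma")
  expect_error(component_density(0, -1, 0, 1, 0), "non-negative")
})

test_that("trimodal density is the pointwise sum of its components", {
  x <- seq(-200, 199, by = 1) + 0.5
  p <- ref_params()
  m <- rbind(c(p[1:4]), c(p[5:7], 0), c(p[8:11]))
  by_hand <- rowSums(sapply(1:3, function(i)
    component_density(x, m[i, 1], m[i, 2], m[i, 3], m[i, 4])))
  expect_equal(trimodal_density(x, p), by_hand)

  # zero amplitudes vanish / reduce to the remaining component
  p0 <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5), c(0, 60, 5, 0))
  expect_equal(trimodal_density(x, p0), rep(0, length(x)))
  p1 <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5), c(78, 61.5, 8.6, 2.8))
  expect_equal(trimodal_density(x, p1),
               component_density(x, 78, 61.5, 8.6, 2.8))
})

test_that("reference parameters produce three ordered peaks", {
  x <- seq(-200, 200, by = 0.1)
  y <- trimodal_density(x, ref_params())
  ds <- diff(sign(diff(y)))
  peaks <- x[which(ds == -2) + 1L]
  peaks <- peaks[y[match(peaks, x)] > 1e-3 * max(y)]
  expect_length(peaks, 3L)
  expect_true(all(diff(peaks) > 0))
  # modes sit in their tissue domains, shifted inward from the locations
  # by the skew (fat alpha < 0 pushes its mode up, muscle alpha > 0 down)
  expect_true(peaks[1] > -125 && peaks[1] < -110)
  expect_true(peaks[2] > -30 && peaks[2] < -18)
  expect_true(peaks[3] > 50 && peaks[3] < 62)
})

test_that("component mass equals the amplitude, confirmed by quadrature", {
  expect_identical(component_mass(1, 0, 1, 0), 1)
  expect_identical(component_mass(5, 42, 7, -3), 5)
  num <- integrate(function(x) component_density(x, 62, -117.8, 8.2, -2.5),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(num, 62, tolerance = 1e-6)
  withr::with_seed(21, {
    for (i in 1:100) {
      N <- runif(1, 0.5, 120); mu <- runif(1, -150, 150)
      sigma <- runif(1, 0.6, 40); alpha <- runif(1, -9, 9)
      num <- integrate(function(x) component_density(x, N, mu, sigma, alpha),
                       mu - 30 * sigma, mu + 30 * sigma,
                       rel.tol = 1e-9)$value
      expect_equal(num, N, tolerance = 1e-6)
    }
  })
})

test_that("positive skewness yields a tail toward lower HU", {
  # third central moment of the sampled component has sign -sign(alpha)
  muscle_like <- trimodal_params(c(0, -120, 5, 0), c(0, 0, 5),
                                 c(1, 60, 8, 2.8))
  v <- sample_voxels(muscle_like, 5e4, seed = 31)
  expect_lt(mean((v - mean(v))^3), 0)

  fat_like <- trimodal_params(c(1, -120, 8, -2.5), c(0, 0, 5),
                              c(0, 60, 5, 0))
  v <- sample_voxels(fat_like, 5e4, seed = 31)
  expect_gt(mean((v - mean(v))^3), 0)
})

test_that("parameter bundles enforce structure and ordering", {
  expect_error(trimodal_params(c(1, 50, 5, 0), c(1, 0, 5), c(1, 60, 5, 0)),
               "fat < connective < muscle")
  expect_error(trimodal_params(c(1, -120, -5, 0), c(1, 0, 5), c(1, 60, 5, 0)),
               "sigma")
  p <- trimodal_params(c(62, -117.8, 8.2, -2.5), c(41.6, -24.1, 25.1),
                       c(78, 61.5, 8.6, 2.8))
  expect_length(unclass(p), 11L)
  expect_false("conn_alpha" %in% names(p))
  expect_error(as_trimodal_params(c(fat_N = 1)), "missing parameter")
})
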