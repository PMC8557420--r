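test_that("simple-pulse segment density is exponential with rate t_m", {
  expect_equal(segment_pdf_simple(0, 1500), 1500)
  expect_equal(segment_pdf_simple(1 / 1500, 1500), 1500 * exp(-1))
  # mean of the distribution is 1/t_m (quadrature oracle)
  m <- integrate(function(l) l * segment_pdf_simple(l, 1500), 0, Inf)$value
  expect_equal(m, 1 / 1500, tolerance = 1e-8)
  expect_error(segment_pdf_simple(-1, 1500), "non-negative")
  expect_error(segment_pdf_simple(0.001, 0), "positive")
})

test_that("extended-pulse density is the Lomax with shape k+1, scale k/t_m", {
  expect_equal(segment_pdf_extended(0, t_m = 1500, k = 4), 1875)
  # normalization and non-negativity
  total <- integrate(function(l) segment_pdf_extended(l, 1500, 36), 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
  l <- seq(0, 0.02, length.out = 200)
  expect_true(all(segment_pdf_extended(l, 1500, 36) >= 0))
})

test_that("large k recovers the simple pulse; k = 1 the constant-migration forms", {
  l <- seq(0, 0.01, length.out = 101)
  expect_equal(segment_pdf_extended(l, 1500, 1e8),
               segment_pdf_simple(l, 1500), tolerance = 1e-5)
  # k = 1, t_m = 1/m: 2 m^2 / (m + l)^3 and D(l) = m / (m + l)
  m <- 0.002
  expect_equal(segment_pdf_extended(l, t_m = 1 / m, k = 1),
               2 * m^2 / (m + l)^3, tolerance = 1e-12)
  expect_equal(ald_extended(l, t_m = 1 / m, k = 1), m / (m + l),
               tolerance = 1e-12)
})

test_that("segment moments: mean 1/t_m for all k, variance (k+1)/((k-1) t_m^2)", {
  for (k in c(1.5, 2, 36, 1e4)) {
    mom <- segment_moments(1500, k)
    expect_equal(mom$mean, 1 / 1500)
    expect_equal(mom$variance, (k + 1) / ((k - 1) * 1500^2))
  }
  expect_equal(segment_moments(1500, 2)$variance, 3 / 1500^2)
  # variance decreases in k toward the simple-pulse value 1/t_m^2
  v <- vapply(c(2, 10, 100, 1e6), function(k) segment_moments(1500, k)$variance,
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_equal(v[4], 1 / 1500^2, tolerance = 1e-5)
  expect_error(segment_moments(1500, 1), "infinite")
})

test_that("entry-time density is Gamma(k+1, rate k/t_m) with the stated moments", {
  t_m <- 1500; k <- 36
  mean_t <- integrate(function(t) t * segment_time_pdf(t, t_m, k), 0, 2e4)$value
  expect_equal(mean_t, (k + 1) / k * t_m, tolerance = 1e-6)
  expect_equal(integrate(function(t) segment_time_pdf(t, t_m, k), 0, 2e4)$value,
               1, tolerance = 1e-8)
  # constant-migration case: Gamma(shape 2, rate m)
  m <- 1 / 800
  tt <- seq(0, 5000, length.out = 50)
  expect_equal(segment_time_pdf(tt, t_m = 1 / m, k = 1),
               dgamma(tt, shape = 2, rate = m), tolerance = 1e-12)
})

test_that("migration density integrates to alpha and tilts into the time density", {
  t_m <- 1500; k <- 36; alpha <- 0.03
  expect_equal(integrate(function(t) migration_density(t, t_m, k, alpha),
                         0, 2e4)$value, alpha, tolerance = 1e-8)
  # k = 1: alpha * m * exp(-m t)
  m <- 1 / 1200
  tt <- seq(0, 6000, length.out = 40)
  expect_equal(migration_density(tt, t_m = 1 / m, k = 1, alpha = alpha),
               alpha * m * exp(-m * tt), tolerance = 1e-12)
  # t * m(t), renormalized, equals the entry-time density on a grid
  tt <- seq(100, 4000, length.out = 60)
  tilted <- tt * migration_density(tt, t_m, k, alpha)
  norm <- integrate(function(t) t * migration_density(t, t_m, k, alpha),
                    0, 2e4)$value
  expect_equal(tilted / norm, segment_time_pdf(tt, t_m, k), tolerance = 1e-7)
})

test_that("ALD decay curves have the stated closed forms and limits", {
  expect_equal(ald_simple(0, 1500, A = 0.4, c = 0.01), 0.41)
  expect_equal(ald_simple(log(2) / 1500, 1500, A = 1, c = 0), 0.5)
  expect_equal(ald_simple(10, 1500, A = 1, c = 0.02), 0.02, tolerance = 1e-6)
  expect_equal(ald_extended(0, 1500, 36, A = 0.4, c = 0.01), 0.41)
  l <- seq(0, 0.02, length.out = 101)
  expect_equal(ald_extended(l, 1500, 1e8, A = 0.7, c = 0.01),
               ald_simple(l, 1500, A = 0.7, c = 0.01), tolerance = 1e-5)
  # non-increasing in l
  expect_true(all(diff(ald_extended(l, 1500, 8, A = 1, c = 0.01)) <= 0))
})

test_that("shape/duration conversions are exact inverses with the 4/sqrt(k) law", {
  expect_equal(duration_from_shape(1500, 16), 1500)
  expect_equal(shape_from_duration(1500, 1000), 36)
  for (k in c(1, 5.0625, 36, 1e6))
    expect_equal(shape_from_duration(1500, duration_from_shape(1500, k)), k)
  expect_lt(duration_from_shape(1500, 1e10), 0.1)
  expect_error(shape_from_duration(1500, 6001), "k < 1")
})

test_that("generation-to-year conversion", {
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(100, gen_time = 25), 2500)
  expect_equal(generations_to_ky(1000, gen_time = 29), 29)
})

test_that("pulse_params validates and derives its fields", {
  p <- pulse_params(1500, t_d = 1000)
  expect_s3_class(p, "pulse_params")
  expect_equal(p$k, 36)
  expect_equal(pulse_params(1500, k = 16)$t_d, 1500)
  expect_error(pulse_params(-1, k = 2), "positive")
  expect_error(pulse_params(1500, k = 0.5), ">= 1")
  expect_error(pulse_params(1500, k = 2, alpha = 1.5), "0, 1")
  expect_error(pulse_params(1500), "one of")
})
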