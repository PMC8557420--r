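test_that("log-likelihoods match the closed-form densities", {
  expect_equal(loglik_simple(0.002, 1500), log(1500) - 1500 * 0.002)
  s <- fixture_segments(n = 500)
  expect_equal(loglik_extended(s$lengths, 1500, 1e8),
               loglik_simple(s$lengths, 1500), tolerance = 1e-4)
  expect_error(loglik_simple(numeric(0), 1500), "non-empty")
  expect_error(loglik_extended(c(0.001, -1), 1500, 4), "positive")
})

test_that("simple-pulse MLE is 1/mean and agrees with a numeric optimizer", {
  expect_equal(fit_segments_simple(c(0.001, 0.002, 0.003))$t_m, 500)
  expect_equal(fit_segments_simple(rep(1 / 1500, 10))$t_m, 1500)
  s <- fixture_segments(n = 2000, t_d = 1)
  fit <- fit_segments_simple(s$lengths)
  num <- optimize(function(tm) loglik_simple(s$lengths, tm),
                  interval = c(1, 5000), maximum = TRUE)$maximum
  expect_equal(fit$t_m, num, tolerance = 1e-6)
  # out-of-bounds mean is clipped and flagged
  big <- fit_segments_simple(rep(1e-6, 5))
  expect_equal(big$t_m, 5000)
  expect_false(big$converged)
})

test_that("extended-pulse MLE recovers simulated parameters", {
  p <- pulse_params(1500, t_d = 1000)
  s <- simulate_segments(1e4, p, seed = 11)
  fit <- fit_segments_extended(s$lengths)
  expect_equal(fit$t_m, 1500, tolerance = 0.1)
  expect_equal(fit$t_d, 1000, tolerance = 0.3)
  expect_true(fit$converged)
  # simple-pulse data pushes k to its upper bound
  set.seed(2)
  e <- rexp(5000, rate = 1500)
  fit0 <- fit_segments_extended(e)
  expect_gt(fit0$k, 1e8)
  expect_equal(fit0$t_m, 1 / mean(e), tolerance = 0.02)
})

test_that("nesting: extended log-likelihood is never worse than simple", {
  for (seed in 1:4) {
    s <- fixture_segments(n = 800, t_d = c(1, 100, 1000, 2500)[seed],
                          seed = seed)
    ll_s <- fit_segments_simple(s$lengths)$objective
    ll_e <- fit_segments_extended(s$lengths)$objective
    expect_gte(ll_e, ll_s - 1e-4)
  }
})

test_that("bootstrap LRT behaves under null and alternative data", {
  set.seed(22)
  null_data <- rexp(500, rate = 1500)
  res <- lrt_extended_vs_simple(null_data, n_boot = 50, seed = 1)
  expect_s3_class(res, "pulse_lrt")
  expect_gte(res$lr, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_gt(res$p_value, 0.01)  # should not reject strongly under the null
  # determinism under seed
  res2 <- lrt_extended_vs_simple(null_data, n_boot = 50, seed = 1)
  expect_identical(res$null_lr, res2$null_lr)
  # strong alternative: long recent pulse is detected
  alt <- simulate_segments(5000, pulse_params(450, t_d = 800), seed = 2)
  res_alt <- lrt_extended_vs_simple(alt$lengths, n_boot = 50, seed = 3)
  expect_lte(res_alt$p_value, 0.02)
  expect_true(res_alt$reject)
  # single observation carries no information to separate the models
  expect_lt(lrt_extended_vs_simple(0.001, n_boot = 50, seed = 4)$lr, 1e-3)
  expect_error(lrt_extended_vs_simple(null_data, n_boot = 10), "at least 50")
})

test_that("ALD least squares recovers noiseless curves to high precision", {
  g <- seq(5e-4, 0.01, by = 2e-5)
  cv <- simulate_ald_curve(g, t_m = 1500, k = 36, A = 0.5, c = 0.01)
  fit <- fit_ald(cv, "extended", n_iter = 3, seed = 6)
  expect_equal(fit$t_m, 1500, tolerance = 1e-3)
  expect_equal(fit$k, 36, tolerance = 1e-3)
  expect_equal(fit$A, 0.5, tolerance = 1e-3)
  expect_equal(fit$c, 0.01, tolerance = 1e-3)
  # simple model on its own curve
  cvs <- ald_curve(g, ald_simple(g, 1200, A = 0.3, c = 0.005))
  fs <- fit_ald(cvs, "simple", n_iter = 3, seed = 7)
  expect_equal(fs$t_m, 1200, tolerance = 1e-3)
  # extended fit of an exponential curve: k driven to its bound, RSS no worse
  fe <- fit_ald(cvs, "extended", n_iter = 3, seed = 8)
  expect_lte(fe$objective, fs$objective + 1e-12)
  expect_gt(fe$k, 1e8)
  # constant curve: amplitude fitted to ~0
  fc <- fit_ald(ald_curve(g, rep(0.02, length(g))), "simple",
                n_iter = 2, seed = 9)
  expect_lt(fc$A, 1e-6)
})

test_that("normalized RSS difference is non-negative and increases with duration", {
  g <- seq(5e-4, 0.01, by = 2e-5)
  set.seed(31)
  nrss <- vapply(c(1000, 2500), function(t_d) {
    k <- shape_from_duration(1500, t_d)
    cv <- simulate_ald_curve(g, 1500, k, A = 0.5, c = 0.01,
                             noise_sd = 1e-4)
    fs <- fit_ald(cv, "simple", n_iter = 2, seed = 1)
    fe <- fit_ald(cv, "extended", n_iter = 2, seed = 1)
    compare_ald_fits(fs, fe)
  }, numeric(1))
  expect_true(all(nrss >= -1e-8))
  expect_gt(nrss[2], nrss[1])
  # identical fits give 0
  f <- fit_ald(simulate_ald_curve(g, 1500, 36), "extended", n_iter = 1,
               seed = 2)
  expect_equal(compare_ald_fits(f, f), 0)
})
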