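test_that("relative temperature difference and its inverse behave correctly", {
  expect_equal(relative_difference(3.6, 21.25, 3.6), 1.0)
  expect_equal(relative_difference(21.25, 21.25, 3.6), 0.0)
  expect_equal(relative_difference(10, 20, 1), 10 / 19, tolerance = 1e-6)
  expect_error(relative_difference(5, 10, 10), "degenerate")
  # round trip
  for (T in c(-3, 0.5, 4, 12, 19.9))
    expect_equal(temperature_from_theta(
      relative_difference(T, 21.25, 3.6), 21.25, 3.6), T)
})

test_that("closed-form decay models match direct arithmetic", {
  expect_equal(theta_mean_model(0, 55.3), 1.0)
  expect_equal(theta_mean_model(55.3, 55.3), exp(-1))
  expect_equal(theta_mean_model(30, 55.3), exp(-30 / 55.3))
  expect_equal(theta_mean_model(30, 55.3), 0.5812, tolerance = 1e-3)
  expect_error(theta_mean_model(10, -5), "positive")

  # shift-free limit equals the mean model
  t <- seq(0, 100, by = 5)
  expect_equal(theta_shifted_model(t, 60, 0, "surface"),
               theta_mean_model(t, 60))
  expect_equal(theta_shifted_model(t, 60, 0, "core"),
               theta_mean_model(t, 60))
  expect_equal(theta_shifted_model(30, 76.8, 0.04, "core"), 0.7041,
               tolerance = 1e-3)
  expect_equal(theta_shifted_model(0, 41.4, 0.07, "surface"), exp(-0.07))
  # core model exceeds 1 near onset and is not clamped
  expect_gt(theta_shifted_model(0, 76.8, 0.04, "core"), 1)
})

test_that("exponential fit recovers exact and noisy time constants", {
  t <- seq(0, 69, by = 3)
  fit <- fit_exponential(t, exp(-t / 60))
  expect_equal(fit$tau, 60, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # halving in 30 minutes determines tau = 30/ln 2 exactly
  fit2 <- fit_exponential(c(0, 30, 60), c(1, 0.5, 0.25))
  expect_equal(fit2$tau, 30 / log(2), tolerance = 1e-6)

  cur <- generate_model_curves(noise_sd = 0.003, seed = 7L)
  fit3 <- fit_exponential(cur$t_min, cur$theta_mean)
  expect_rel_error(fit3$tau, 55.3, 0.02)
  expect_gt(fit3$sd_tau, 0)

  expect_error(fit_exponential(c(0, 3), c(1, 0.9)), "at least 3")
  expect_error(fit_exponential(c(0, 3, 3), c(1, 0.9, 0.8)), "increasing")
  expect_error(fit_exponential(c(0, 3, 6), c(1, NA, 0.8)), "non-finite")
})

test_that("shifted-exponential fit recovers (tau, delta) jointly", {
  t <- seq(0, 69, by = 3)
  core <- fit_shifted_exponential(t, theta_shifted_model(t, 76.8, 0.04, "core"),
                                  "core")
  expect_equal(core$tau, 76.8, tolerance = 1e-6)
  expect_equal(core$delta, 0.04, tolerance = 1e-6)
  expect_equal(core$r2, 1, tolerance = 1e-9)

  surf <- fit_shifted_exponential(
    t, theta_shifted_model(t, 41.4, 0.07, "surface"), "surface")
  expect_equal(surf$tau, 41.4, tolerance = 1e-6)
  expect_equal(surf$delta, 0.07, tolerance = 1e-6)

  cur <- generate_model_curves(noise_sd = 0.003, seed = 11L)
  noisy <- fit_shifted_exponential(cur$t_min, cur$theta_core, "core")
  expect_rel_error(noisy$tau, 76.8, 0.03)
  expect_lt(abs(noisy$delta - 0.04), 0.01)
  expect_equal(dim(noisy$covariance), c(2L, 2L))
  expect_false(noisy$delta_at_boundary)
})

test_that("t_spread closed form matches the brute-force argmax", {
  fit <- cohort_reference_fit()
  expect_equal(t_spread(fit), 45.62, tolerance = 1e-3)

  # 100 random valid parameter sets against a dense grid search
  set.seed(301)
  tg <- seq(0, 200, by = 0.01)
  for (i in 1:100) {
    ts <- runif(1, 20, 60); tc <- ts + runif(1, 5, 60)
    ds <- runif(1, 0, 0.15); dc <- runif(1, 0, 0.1)
    f <- suppressWarnings(warmup_fit((ts + tc) / 2, ts, tc, ds, dc))
    t_closed <- t_spread(f)
    if (t_closed < 0 || t_closed > 200) next  # argmax outside the grid span
    t_grid <- tg[which.max(theta_spread(tg, f))]
    expect_lt(abs(t_closed - t_grid), 0.01)
  }

  f_deg <- suppressWarnings(warmup_fit(50, 45, 45.000, 0.05, 0.03))
  expect_error(t_spread(f_deg), "interior maximum")
})

test_that("theta_spread evaluates the core-surface gap", {
  fit <- cohort_reference_fit()
  expect_lt(theta_spread(1000, fit), 1e-4)
  expect_equal(theta_spread(t_spread(fit), fit), 0.2649, tolerance = 1e-3)
  expect_equal(theta_spread(0, fit), exp(0.04) - exp(-0.07), tolerance = 1e-6)
  d <- derived_constants(fit)
  expect_equal(d$ratio_sm, 41.4 / 55.3)
  expect_equal(d$ratio_sc, 41.4 / 76.8)
  expect_gt(d$ratio_sm, d$ratio_sc)
})

test_that("surface-based predictions satisfy the time-elimination identities", {
  fit <- cohort_reference_fit()
  expect_equal(predict_mean_from_surface(exp(-0.07), fit), 1.0,
               tolerance = 1e-12)
  expect_equal(predict_mean_from_surface(0.5, fit), 0.6272, tolerance = 1e-4)
  expect_equal(predict_core_from_surface(0.5, fit), 0.7438, tolerance = 1e-4)
  expect_equal(predict_core_from_surface(exp(-0.07), fit), exp(0.04),
               tolerance = 1e-12)
  # for any t, predicting from theta_surface(t) reproduces the other curves
  for (t in c(0, 7.5, 30, 45.62, 69, 120)) {
    th_s <- theta_shifted_model(t, fit$tau_surface, fit$delta_surface,
                                "surface")
    expect_equal(predict_mean_from_surface(th_s, fit),
                 theta_mean_model(t, fit$tau_mean), tolerance = 1e-12)
    expect_equal(predict_core_from_surface(th_s, fit),
                 theta_shifted_model(t, fit$tau_core, fit$delta_core, "core"),
                 tolerance = 1e-12)
  }
  expect_error(predict_mean_from_surface(0, fit), "positive")
})

test_that("model curves are ordered and decreasing for sensible fits", {
  set.seed(302)
  t <- seq(0, 150, by = 1.5)
  for (i in 1:25) {
    tm <- runif(1, 40, 70)
    f <- suppressWarnings(warmup_fit(tm, tm * runif(1, 0.6, 0.9),
                                     tm * runif(1, 1.2, 1.6),
                                     runif(1, 0, 0.12), runif(1, 0, 0.08)))
    th_s <- theta_shifted_model(t, f$tau_surface, f$delta_surface, "surface")
    th_m <- theta_mean_model(t, f$tau_mean)
    th_c <- theta_shifted_model(t, f$tau_core, f$delta_core, "core")
    expect_true(all(diff(th_s) < 0) && all(diff(th_m) < 0) &&
                all(diff(th_c) < 0))
    expect_true(all(th_s <= th_m + 1e-12) && all(th_m <= th_c + 1e-12))
  }
})

test_that("time-to-threshold inverts each curve", {
  fit <- cohort_reference_fit()
  expect_equal(time_to_threshold(10, 1, 20, fit, "core"), 52.4,
               tolerance = 1e-3)
  expect_equal(round(time_to_threshold(10, 1, 20, fit, "core")), 52)
  expect_equal(time_to_threshold(10, 1, 20, fit, "mean"), 35.49,
               tolerance = 1e-2)
  # mean curve: threshold at storage temperature is reached at exactly t = 0
  expect_equal(time_to_threshold(1 + 1e-12, 1, 20, fit, "mean"), 0,
               tolerance = 1e-6)
  # consistency: evaluating the curve at the returned time recovers theta*
  for (wh in c("mean", "core")) {
    tt <- time_to_threshold(8, 2, 21.25, fit, wh)
    th <- switch(wh, mean = theta_mean_model(tt, fit$tau_mean),
                 core = theta_shifted_model(tt, fit$tau_core, fit$delta_core,
                                            "core"))
    expect_equal(th, relative_difference(8, 21.25, 2), tolerance = 1e-10)
  }
  expect_error(time_to_threshold(25, 1, 20, fit, "core"), "strictly between")
})

test_that("limiting ambient temperature reproduces the 30-minute-rule bounds", {
  fit <- cohort_reference_fit()
  expect_equal(round(limit_ambient(1, 30, 10, fit, "core")), 31)
  expect_equal(limit_ambient(1, 30, 10, fit, "core"), 31.43, tolerance = 1e-2)
  expect_equal(limit_ambient(6, 30, 10, fit, "core"), 19.52, tolerance = 1e-2)
  # threshold equal to storage returns storage for any theta* < 1
  expect_equal(limit_ambient(4, 30, 4, fit, "core"), 4, tolerance = 1e-12)
  expect_error(limit_ambient(1, 0, 10, fit, "core"), "positive")
  # core theta exceeds 1 at onset: no finite limit
  expect_error(limit_ambient(1, 0.1, 10, fit, "core"), "finite ambient")
})

test_that("uncertainty propagation matches closed form and Monte Carlo", {
  fit <- cohort_reference_fit()
  zero <- warmup_fit(55.3, 41.4, 76.8, 0.07, 0.04)
  band0 <- propagate_uncertainty(zero, seq(0, 69, by = 3))
  expect_true(all(band0$sigma_mean == 0) && all(band0$sigma_surface == 0) &&
              all(band0$sigma_core == 0))

  band <- propagate_uncertainty(fit, 55.3)
  expect_equal(band$sigma_mean, exp(-1) * 3.7 / 55.3, tolerance = 1e-6)

  # Monte Carlo oracle: 1e5 parameter draws
  set.seed(303)
  n <- 1e5
  tg <- c(10, 30, 55.3, 69)
  band_g <- propagate_uncertainty(fit, tg)
  tau_m <- rnorm(n, fit$tau_mean, fit$sd_tau_mean)
  tau_c <- rnorm(n, fit$tau_core, fit$sd_tau_core)
  del_c <- rnorm(n, fit$delta_core, fit$sd_delta_core)
  for (i in seq_along(tg)) {
    mc_mean <- sd(exp(-tg[i] / tau_m))
    mc_core <- sd(exp(-(tg[i] / tau_c - del_c)))
    if (band_g$sigma_mean[i] > 0.005)
      expect_rel_error(band_g$sigma_mean[i], mc_mean, 0.05)
    if (band_g$sigma_core[i] > 0.005)
      expect_rel_error(band_g$sigma_core[i], mc_core, 0.05)
  }
})

test_that("warmup_fit validates inputs and warns on implausible ordering", {
  expect_warning(warmup_fit(50, 60, 70, 0.05, 0.03), "tau_surface")
  expect_error(warmup_fit(-5, 40, 70, 0.05, 0.03), "positive")
  expect_error(warmup_fit(55, 40, 70, -0.1, 0.03), "non-negative")
  f <- cohort_reference_fit()
  expect_output(print(f), "tau_mean")
})
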