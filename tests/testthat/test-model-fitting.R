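test_that("the initial state comes from block 1 by the model inverse", {
  ser <- probe_series(c(13, 13, 13, 13, 13), c(13, 13, 13, 13, 13),
                      c(0, 0, 0, 0, 0), "CTS_in")
  expect_equal(unclass(initial_gain_state(ser)),
               c(omega_v = 1, omega_m = 1, omega_cd = 1))
  ser2 <- probe_series(c(13, 13, 13, 13, 13), c(12.4, 13, 13, 13, 13),
                       c(0.8, 0, 0, 0, 0), "CTS_in")
  expect_equal(unclass(initial_gain_state(ser2)),
               c(omega_v = 1, omega_m = 12.4 / 13, omega_cd = 12.2 / 12.4),
               tolerance = 1e-12)
  ser3 <- probe_series(c(0, 13, 13, 13, 13), rep(13, 5), rep(0, 5), "CTS_in")
  expect_error(initial_gain_state(ser3), "degenerate")
})

test_that("the weighted objective is zero iff the model threads the data", {
  a_true <- c(2e-6, 1.5e-5, 8e-6)
  ser <- simulate_probe_series(baseline_gain_state(), a_true, "CTS_in")
  expect_equal(probe_objective(a_true, ser, "postdiction"), 0,
               tolerance = 1e-18)
  expect_gt(probe_objective(c(0, 0, 0), ser, "postdiction"), 0)

  # perturbing block 3's saccade vector by +1 deg adds exactly eta * 1^2
  pert <- ser
  pert$M[3L] <- pert$M[3L] + 1
  expect_equal(probe_objective(a_true, pert, "postdiction"), 0.65,
               tolerance = 1e-9)
  # and the long-block weight applies at block 5
  pert5 <- ser
  pert5$V2_hat[5L] <- pert5$V2_hat[5L] - 2
  expect_equal(probe_objective(a_true, pert5, "postdiction"), 1.52 * 4,
               tolerance = 1e-9)
})

test_that("diverging rates are penalized, not propagated", {
  ser <- simulate_probe_series(gain_state(1, 1.5, 0.2),
                               c(2e-6, 1.5e-5, 8e-6), "CTS_out")
  cfg <- fit_config(alpha_upper = 5e-3)
  val <- probe_objective(c(5e-3, 5e-3, 5e-3), ser, "postdiction", cfg)
  expect_equal(val, cfg$penalty)
})

test_that("fitting recovers generating rates from noiseless probe data", {
  for (cond in c("CTS_in", "CVE_out")) {
    a_true <- c(2e-6, 1.5e-5, 8e-6)
    ser <- simulate_probe_series(baseline_gain_state(), a_true, cond)
    fit <- fit_learning_rates(ser, "postdiction")
    expect_equal(unname(unclass(fit$alpha)), a_true, tolerance = 0.01)
    expect_lt(fit$sse, 1e-10)
    expect_equal(fit$rse, sqrt(fit$sse / 14))
    expect_true(all(unclass(fit$alpha) >= 0 & unclass(fit$alpha) <= 9e-5))
  }
})

test_that("a constant series is fitted by (near) zero learning", {
  ser <- probe_series(rep(13, 5), rep(12.4, 5), rep(0.8, 5), "baseline")
  fit <- fit_learning_rates(ser, "postdiction")
  expect_lt(fit$sse, 1e-10)
})

test_that("shared-rate fits pool two conditions of one direction", {
  a_true <- c(2e-6, 1.5e-5, 8e-6)
  s_cts <- simulate_probe_series(baseline_gain_state(), a_true, "CTS_in")
  s_cve <- simulate_probe_series(baseline_gain_state(), a_true, "CVE_in")
  sh <- fit_shared_rates(s_cts, s_cve, "postdiction")
  expect_equal(unname(unclass(sh$alpha)), a_true, tolerance = 0.01)
  expect_lt(sh$cts$sse + sh$cve$sse, 1e-9)

  # the shared optimum can never beat the per-condition optimum
  a_other <- c(4e-6, 3e-5, 4e-6)
  s_cve2 <- simulate_probe_series(baseline_gain_state(), a_other, "CVE_in")
  sh2 <- fit_shared_rates(s_cts, s_cve2, "postdiction")
  f_cts <- fit_learning_rates(s_cts, "postdiction")
  f_cve2 <- fit_learning_rates(s_cve2, "postdiction")
  expect_gte(sh2$cts$rse + 1e-12, f_cts$rse)
  expect_gte(sh2$cve$rse + 1e-12, f_cve2$rse)

  # identical series in both slots reproduce the single fit
  sh3 <- fit_shared_rates(s_cts, s_cts, "postdiction")
  expect_equal(unclass(sh3$alpha), unclass(f_cts$alpha), tolerance = 1e-4)
  expect_error(fit_shared_rates(s_cts,
                                simulate_probe_series(baseline_gain_state(),
                                                      a_true, "CVE_out"),
                                "postdiction"),
               "direction")
})

test_that("prediction-mode fits to postdiction data are strictly worse", {
  ser <- simulate_probe_series(baseline_gain_state(),
                               default_rates("CTS_in"), "CTS_in")
  f_post <- fit_learning_rates(ser, "postdiction")
  f_pre <- fit_learning_rates(ser, "prediction")
  expect_gt(f_pre$rse, f_post$rse)
  expect_gt(f_pre$rse, 10 * f_post$rse)  # not a marginal difference
})

test_that("steady-state error metrics follow their definitions", {
  # unity initial gains: baseline error zero in both modes
  for (mode in c("prediction", "postdiction")) {
    tr <- simulate_learning(gain_state(1, 1, 1), learning_rates(0, 0, 0),
                            condition_paradigm("CTS_in"), 281, mode)
    m <- error_metrics(tr)
    expect_equal(m$baseline_error, 0)
    expect_equal(m$first_error, -3)
    expect_equal(m$pct_decline, 0)
  }
  # hypometric initial gains: baseline postdictive error from the closed form
  st <- gain_state(1.0, 12.4 / 13, 12.2 / 12.4)
  tr <- simulate_learning(st, learning_rates(0, 0, 0),
                          condition_paradigm("CTS_in"), 281, "postdiction")
  expect_equal(error_metrics(tr)$baseline_error, 0.4, tolerance = 1e-9)
  # CDV error and endpoint error columns
  expect_equal(error_metrics(tr)$cdv_error_first, 12.2 - 12.4,
               tolerance = 1e-9)
  expect_equal(error_metrics(tr)$V2_first, 13 - 12.4 - 3, tolerance = 1e-9)

  # a (nearly) converged postdiction run declines (nearly) 100%
  tr <- simulate_learning(baseline_gain_state(),
                          learning_rates(5.2e-6, 3.5e-5, 1.8e-5),
                          condition_paradigm("CTS_in"), 5000, "postdiction")
  expect_gt(error_metrics(tr)$pct_decline, 99.9)
})

test_that("paired RSE comparison reduces to the paired t-test", {
  # differences (0.3, 0.5, 0.4): mean 0.4, sd 0.1, t = mean/(sd/sqrt(3))
  expect_equal(compare_models(c(0.5, 0.6, 0.4), c(0.2, 0.1, 0.0))$t,
               0.4 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(compare_models(c(0.5, 0.6, 0.4), c(0.2, 0.1, 0.0))$df, 2)
  same <- compare_models(c(0.5, 0.6), c(0.5, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$mean_diff, 0)
  expect_error(compare_models(0.4, c(0.1, 0.2)), "unmatched")
  expect_error(compare_models(0.4, 0.1), "2 subjects")
})
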