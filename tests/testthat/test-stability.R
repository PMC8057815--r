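test_that("fixed-point planes solve the zero-error condition", {
  expect_equal(fixed_point_omega_m(1, 1, paradigm("BASELINE")), 1)
  expect_equal(fixed_point_omega_m(1, 1, condition_paradigm("CTS_in")),
               10 / 13, tolerance = 1e-12)
  # CVE with Ps = 0 has only the degenerate algebraic branch omega_m = 0
  expect_equal(fixed_point_omega_m(1.2, 0.7, paradigm("CVE", 13, 0)), 0)
  expect_error(fixed_point_omega_m(1, 2, condition_paradigm("CTS_in")),
               "singular")
  expect_error(fixed_point_omega_m(1, 1, condition_paradigm("CVE_in")),
               "singular")
  expect_error(fixed_point_omega_m(0, 1.2, condition_paradigm("CTS_in")),
               "singular")
})

test_that("substituting the plane into the postdictive error nullifies it", {
  wv_grid <- seq(0.8, 1.2, length.out = 9)
  wcd_grid <- seq(0.52, 1.48, length.out = 8)  # avoids the CVE pole at 1
  for (cond in c("CTS_in", "CTS_out", "CVE_in", "CVE_out")) {
    p <- condition_paradigm(cond)
    for (wv in wv_grid) for (wcd in wcd_grid) {
      wm <- fixed_point_omega_m(wv, wcd, p)
      e <- error_signal(gain_state(wv, wm, wcd), p, "postdiction")
      expect_lt(abs(e), 1e-12)
      # and the dynamics are stationary there
      expect_equal(unname(gain_step(gain_state(wv, wm, wcd),
                                    default_rates(cond), p)),
                   c(0, 0, 0), tolerance = 1e-15)
    }
  }
})

test_that("the per-trial gain change follows -2 alpha E grad", {
  p <- condition_paradigm("CTS_in")
  step <- gain_step(gain_state(1, 1, 1), learning_rates(1e-6, 1e-6, 1e-6), p)
  expect_equal(unname(step), c(-7.8e-5, -7.8e-5, 7.8e-5), tolerance = 1e-12)
  expect_equal(unname(gain_step(gain_state(1.1, 0.8, 0.9),
                                learning_rates(0, 0, 0), p)),
               c(0, 0, 0))
})

test_that("the analytic Jacobian matches central finite differences", {
  W <- rand_states(60, seed = 31)
  a <- learning_rates(3e-6, 2e-5, 1e-5)
  cases <- list(list(p = condition_paradigm("CTS_in"), clamp = TRUE),
                list(p = condition_paradigm("CVE_out"), clamp = TRUE),
                list(p = condition_paradigm("CVE_out"), clamp = FALSE))
  for (cs in cases) {
    for (i in seq_len(nrow(W))) {
      st <- gain_state(W[i, 1], W[i, 2], W[i, 3])
      J <- learning_jacobian(st, a, cs$p, pd_clamped = cs$clamp)
      Jfd <- learning_jacobian(st, a, cs$p, pd_clamped = cs$clamp,
                               numeric = TRUE)
      expect_equal(J, Jfd, tolerance = 1e-6)
    }
  }
})

test_that("fixed points are rank-1 attracting transverse to the plane", {
  a <- learning_rates(3e-6, 2e-5, 1e-5)
  for (cond in c("CTS_in", "CTS_out")) {
    p <- condition_paradigm(cond)
    for (wcd in c(0.7, 0.95, 1.3)) {
      wv <- 1.05
      st <- gain_state(wv, fixed_point_omega_m(wv, wcd, p), wcd)
      J <- learning_jacobian(st, a, p)
      g <- unname(error_gradient(st, p, "postdiction"))
      # E = 0 there, so J = -2 diag(alpha) g g^T
      expect_equal(J, -2 * diag(unclass(a)) %*% (g %*% t(g)),
                   tolerance = 1e-9, ignore_attr = TRUE)
      rep_ <- classify_stability(J, tol = 1e-9)
      expect_identical(rep_$label, "stable")
      ev <- sort(Re(rep_$eigenvalues))
      # two zero eigenvalues along the plane, one strictly negative
      expect_equal(ev[2:3], c(0, 0), tolerance = 1e-9)
      expect_equal(ev[1], -2 * sum(unclass(a) * g^2), tolerance = 1e-9)
      expect_lt(ev[1], 0)
    }
  }
  # degenerate and constructed cases
  expect_identical(classify_stability(matrix(0, 3, 3))$label, "marginal")
  expect_identical(classify_stability(diag(c(1e-3, -1, -1)))$label, "unstable")
  expect_identical(classify_stability(diag(c(0, -1, -2)))$label, "stable")
})

test_that("the planar vector field vanishes on the curve and scales with alpha", {
  p <- condition_paradigm("CTS_in")
  a <- learning_rates(3e-6, 2e-5, 1e-5)
  wv <- 1
  wcd <- c(0.8, 1.0, 1.2)
  wm_curve <- fixed_point_omega_m(wv, wcd, p)
  vf <- vector_field(omega_m = wm_curve[2], omega_cd = wcd[2], wv, a, p)
  expect_equal(vf$d_omega_m, 0, tolerance = 1e-15)
  expect_equal(vf$d_omega_cd, 0, tolerance = 1e-15)

  # arrows point toward the curve in omega_m on either side of it
  right <- vector_field(wm_curve[2] + 0.1, wcd[2], wv, a, p)
  left <- vector_field(wm_curve[2] - 0.1, wcd[2], wv, a, p)
  expect_lt(right$d_omega_m, 0)
  expect_gt(left$d_omega_m, 0)

  # doubling every rate doubles every arrow
  grid_m <- seq(0.6, 1.2, length.out = 5)
  v1 <- vector_field(grid_m, wcd, wv, a, p)
  v2 <- vector_field(grid_m, wcd, wv,
                     learning_rates(6e-6, 4e-5, 2e-5), p)
  expect_equal(v2$d_omega_m, 2 * v1$d_omega_m, tolerance = 1e-12)
  expect_equal(v2$d_omega_cd, 2 * v1$d_omega_cd, tolerance = 1e-12)
})

test_that("converged simulations terminate on the fixed-point plane", {
  for (cond in c("CTS_in", "CTS_out", "CVE_in")) {
    p <- condition_paradigm(cond)
    tr <- simulate_learning(baseline_gain_state(), default_rates(cond),
                            p, 1e4, "postdiction")
    n <- nrow(tr)
    wm_fp <- fixed_point_omega_m(tr$omega_v[n], tr$omega_cd[n], p)
    expect_lt(abs(tr$omega_m[n] - wm_fp), 1e-3)
  }
})
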