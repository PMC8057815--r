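#' Fit configuration
#'
#' Settings for the bounded weighted least-squares fit of the learning
#' rates. The box constraints `[alpha_lower, alpha_upper]` default to the
#' study bounds `[0, 9e-5]`; `lambda` is the number of data points entering
#' the residual standard error (five probe blocks times three observables).
#'
#' @param alpha_lower,alpha_upper Box bounds on each learning rate.
#' @param lambda Number of fitted data points (15).
#' @param n_starts Number of deterministic multistarts (>= 2): the zero
#'   corner plus points log-spaced across the box. The objective has
#'   near-flat plateaus at very small rates, so multistart matters.
#' @param cap Divergence guard on |gain| during simulation.
#' @param penalty Objective value (deg^2) returned for diverged simulations;
#'   large and finite so bounded optimizers stay in the stable region.
#' @param factr,pgtol `stats::optim` L-BFGS-B tolerances.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(alpha_lower = 0, alpha_upper = 9e-5, lambda = 15L,
                       n_starts = 8L, cap = 10, penalty = 1e6,
                       factr = 1e4, pgtol = 0) {
  stopifnot(alpha_lower >= 0, alpha_upper > alpha_lower, n_starts >= 2L)
  structure(list(alpha_lower = alpha_lower, alpha_upper = alpha_upper,
                 lambda = as.integer(lambda), n_starts = as.integer(n_starts),
                 cap = cap, penalty = penalty, factr = factr, pgtol = pgtol),
            class = "fit_config")
}

#' Initial gain state from the baseline probe block
#'
#' Derives the trial-1 gain state from the first probe block's medians via
#' the algebraic inverse of the forward model ([derive_gains()]).
#'
#' @param series A [probe_series()].
#' @return A [gain_state()].
#' @export
initial_gain_state <- function(series) {
  stopifnot(inherits(series, "probe_series"))
  P1 <- attr(series, "paradigm")$P1
  g <- derive_gains(series$V1[1L], series$M[1L], series$V2_hat[1L], P1)
  gain_state(g$omega_v, g$omega_m, g$omega_cd)
}

# predicted (V1, M, V2_hat) at the probe trials for given rates; NULL if the
# simulation diverged
.probe_predictions <- function(alpha, series, mode, cap) {
  p <- attr(series, "paradigm")
  w0 <- unclass(initial_gain_state(series))
  sim <- .simulate_core(w0, alpha, p$P1, p$Ps, p$kind == "CVE",
                        281L, mode, cap)
  if (sim$diverged) return(NULL)
  g <- sim$gains[series$trial, , drop = FALSE]
  V1 <- p$P1 * g[, 1L]
  M <- V1 * g[, 2L]
  CDV <- M * g[, 3L]
  list(V1 = V1, M = M, V2_hat = V1 - CDV)
}

#' Weighted sum-of-squares objective
#'
#' Simulates 281 trials from the block-1 gain state under the given error
#' mode and accumulates, at the probe trials `[1, 71, 141, 211, 281]`, the
#' block-weighted squared deviations of the predicted pre-saccadic
#' localization, saccade vector and post-saccadic localization from the
#' measured medians:
#' \eqn{\sum_n \eta(n)[(V_1-V_1^{pred})^2 + (M-M^{pred})^2 +
#' (\hat V_2-\hat V_2^{pred})^2]}.
#' Diverged simulations return the configured penalty value.
#'
#' @param alpha Learning rates (numeric 3-vector or [learning_rates()]).
#' @param series A [probe_series()].
#' @param mode Error mode.
#' @param config A [fit_config()].
#' @return Weighted SSE in deg^2.
#' @export
probe_objective <- function(alpha, series,
                            mode = c("prediction", "postdiction", "visual"),
                            config = fit_config()) {
  mode <- match.arg(mode)
  alpha <- as.numeric(alpha)
  pred <- .probe_predictions(alpha, series, mode, config$cap)
  if (is.null(pred)) return(config$penalty)
  sum(series$eta * ((series$V1 - pred$V1)^2 +
                    (series$M - pred$M)^2 +
                    (series$V2_hat - pred$V2_hat)^2))
}

# deterministic multistart set on the unit cube (alpha / alpha_upper)
.start_points <- function(n_starts) {
  # zero corner, then log-spaced diagonal and off-diagonal points
  diag_levels <- 10^seq(-3.5, -0.05, length.out = max(3L, n_starts - 4L))
  starts <- rbind(c(0, 0, 0),
                  t(vapply(diag_levels, function(s) rep(s, 3), numeric(3))),
                  c(1e-2, 3e-1, 1e-1),   # motor-dominant, the typical pattern
                  c(1e-1, 1e-2, 1e-1),
                  c(3e-1, 3e-1, 1e-3))
  starts[seq_len(min(nrow(starts), max(n_starts, 4L))), , drop = FALSE]
}

# multistart bounded minimization over scaled rates s = alpha/alpha_upper
.minimize_rates <- function(fn, config) {
  starts <- .start_points(config$n_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                        lower = config$alpha_lower / config$alpha_upper,
                        upper = 1,
                        control = list(factr = config$factr,
                                       pgtol = config$pgtol,
                                       maxit = 500L,
                                       ndeps = rep(1e-7, 3)))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (best$value >= config$penalty)
    stop("non-convergence: all starts diverged", call. = FALSE)
  # guard against sub-epsilon bound violations from the optimizer
  best$par <- pmin(pmax(best$par, config$alpha_lower / config$alpha_upper), 1)
  best
}

#' Fit the learning rates to a probe series
#'
#' Minimizes [probe_objective()] over the box `[0, 9e-5]^3` by L-BFGS-B with
#' a deterministic multistart, starting each simulation from the gain state
#' derived from probe block 1. Returns the fitted rates with the trajectory,
#' the weighted SSE, the residual standard error
#' `RSE = sqrt(SSE/(lambda - 1))`, and the steady-state error metrics.
#'
#' @param series A [probe_series()].
#' @param mode Error mode driving learning in the fitted model.
#' @param config A [fit_config()].
#' @return An object of class `"saccade_fit"`: list with elements `alpha`
#'   ([learning_rates()]), `sse`, `rse`, `trajectory`, `initial_state`,
#'   `metrics` (see [error_metrics()]), `mode`, `series`, `convergence`.
#' @seealso [fit_shared_rates()], [compare_models()]
#' @export
fit_learning_rates <- function(series,
                               mode = c("prediction", "postdiction", "visual"),
                               config = fit_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "probe_series"))
  fn <- function(s) probe_objective(s * config$alpha_upper, series, mode, config)
  best <- .minimize_rates(fn, config)
  alpha <- learning_rates(best$par[1L] * config$alpha_upper,
                          best$par[2L] * config$alpha_upper,
                          best$par[3L] * config$alpha_upper)
  .finish_fit(alpha, best, series, mode, config)
}

.finish_fit <- function(alpha, best, series, mode, config) {
  p <- attr(series, "paradigm")
  w0 <- initial_gain_state(series)
  traj <- simulate_learning(w0, alpha, p, 281L, mode, cap = config$cap,
                            divergence = "flag")
  sse <- probe_objective(unclass(alpha), series, mode, config)
  structure(list(alpha = alpha,
                 sse = sse,
                 rse = sqrt(sse / (config$lambda - 1L)),
                 trajectory = traj,
                 initial_state = w0,
                 metrics = error_metrics(traj),
                 mode = mode,
                 series = series,
                 convergence = best$convergence),
            class = "saccade_fit")
}

#' @export
print.saccade_fit <- function(x, ...) {
  cat(sprintf("<saccade_fit> mode = %s\n", x$mode))
  cat(sprintf("  alpha = (%.3g, %.3g, %.3g) 1/deg^2\n",
              x$alpha[[1L]], x$alpha[[2L]], x$alpha[[3L]]))
  cat(sprintf("  SSE = %.4g deg^2, RSE = %.4g deg\n", x$sse, x$rse))
  m <- x$metrics
  cat(sprintf("  baseline error %.3g deg, final error %.3g deg, decline %.1f%%\n",
              m$baseline_error, m$final_error, m$pct_decline))
  invisible(x)
}

#' Shared-rate fit over a CTS and a CVE series
#'
#' Fits a single learning-rate vector that minimizes the sum of the two
#' weighted SSEs over the paired CTS and CVE sessions of one subject (same
#' learning direction), as in the pooled-condition analysis. Per-condition
#' SSE/RSE and trajectories are reported for the shared optimum.
#'
#' @param series_cts,series_cve [probe_series()] objects of the two
#'   paradigms, same step direction.
#' @param mode Error mode.
#' @param config A [fit_config()].
#' @return List with `alpha` and elements `cts`, `cve`, each a
#'   `"saccade_fit"` evaluated at the shared rates.
#' @export
fit_shared_rates <- function(series_cts, series_cve,
                             mode = c("prediction", "postdiction", "visual"),
                             config = fit_config()) {
  mode <- match.arg(mode)
  p1 <- attr(series_cts, "paradigm"); p2 <- attr(series_cve, "paradigm")
  if (sign(p1$Ps) != sign(p2$Ps))
    stop("shared fit requires the same step direction", call. = FALSE)
  fn <- function(s) {
    a <- s * config$alpha_upper
    probe_objective(a, series_cts, mode, config) +
      probe_objective(a, series_cve, mode, config)
  }
  best <- .minimize_rates(fn, config)
  alpha <- learning_rates(best$par[1L] * config$alpha_upper,
                          best$par[2L] * config$alpha_upper,
                          best$par[3L] * config$alpha_upper)
  list(alpha = alpha,
       cts = .finish_fit(alpha, best, series_cts, mode, config),
       cve = .finish_fit(alpha, best, series_cve, mode, config))
}

#' Steady-state error metrics of a fitted trajectory
#'
#' Computes, for a learning trajectory: the baseline error (error-mode value
#' at the trial-1 gains with no target step, i.e. CTS with `Ps = 0`), the
#' first-trial error including the step, the final error at trial 281, the
#' percentage of error decline `100 (1 - |E(281)|/|E(1)|)`, the CDV error
#' `CDV - M` at trials 1 and 281, and the visual endpoint error `V2` at
#' trials 1 and 281.
#'
#' @param trajectory A `"trajectory"` from [simulate_learning()] (or the
#'   `trajectory` element of a `"saccade_fit"`).
#' @return One-row data frame of metrics (degrees, or percent for
#'   `pct_decline`).
#' @export
error_metrics <- function(trajectory) {
  if (inherits(trajectory, "saccade_fit")) trajectory <- trajectory$trajectory
  stopifnot(inherits(trajectory, "trajectory"))
  mode <- attr(trajectory, "mode")
  p <- attr(trajectory, "paradigm")
  n <- nrow(trajectory)
  w1 <- gain_state(trajectory$omega_v[1L], trajectory$omega_m[1L],
                   trajectory$omega_cd[1L])
  base <- error_signal(w1, paradigm("CTS", p$P1, 0), mode)
  e1 <- trajectory$error[1L]
  eN <- trajectory$error[n]
  data.frame(baseline_error = base,
             first_error = e1,
             final_error = eN,
             pct_decline = if (e1 == 0) NA_real_ else 100 * (1 - abs(eN) / abs(e1)),
             cdv_error_first = trajectory$CDV[1L] - trajectory$M[1L],
             cdv_error_final = trajectory$CDV[n] - trajectory$M[n],
             V2_first = trajectory$V2[1L],
             V2_final = trajectory$V2[n])
}

#' Paired model comparison on residual standard errors
#'
#' Both error models have the same three free parameters, so fit quality is
#' compared directly by a paired two-sided t-test on the per-subject
#' residual standard errors of the prediction- and postdiction-mode fits.
#' A positive mean difference means the prediction model fits worse.
#'
#' @param rse_prediction,rse_postdiction Numeric vectors of per-subject RSEs
#'   (matched order), or lists of `"saccade_fit"` objects.
#' @return List with `t`, `df`, `p`, `mean_diff` (prediction - postdiction).
#' @export
compare_models <- function(rse_prediction, rse_postdiction) {
  as_rse <- function(x)
    if (is.list(x)) vapply(x, function(f) f$rse, numeric(1)) else as.numeric(x)
  a <- as_rse(rse_prediction); b <- as_rse(rse_postdiction)
  if (length(a) != length(b)) stop("unmatched subjects", call. = FALSE)
  if (length(a) < 2L) stop("at least 2 subjects required", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else NA_real_, df = length(d) - 1L,
                p = NA_real_, mean_diff = mean(d)))
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d))
}
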