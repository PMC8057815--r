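#' Learning rates of the delta rule
#'
#' Per-trial learning rates \eqn{(\alpha_v, \alpha_m, \alpha_{cd})} of the
#' diagonal rate matrix. Units are 1/deg^2: each rate multiplies the product
#' of an error (deg) and an error gradient (deg per unit gain). Fitted values
#' are bounded to `[0, 9e-5]`; the lower bound enforces learning in gradient
#' direction, the upper bound prevents the saccade vector from taking a
#' runaway exponential shape over a session.
#'
#' @param alpha_v,alpha_m,alpha_cd Non-negative rates.
#' @return Named numeric vector of class `"learning_rates"`.
#' @examples
#' learning_rates(5.2e-6, 3.5e-5, 1.8e-5)
#' @export
learning_rates <- function(alpha_v = 0, alpha_m = 0, alpha_cd = 0) {
  a <- c(alpha_v = as.numeric(alpha_v), alpha_m = as.numeric(alpha_m),
         alpha_cd = as.numeric(alpha_cd))
  if (!all(is.finite(a)) || any(a < 0))
    stop("learning rates must be finite and non-negative", call. = FALSE)
  structure(a, class = "learning_rates")
}

#' @export
print.learning_rates <- function(x, ...) {
  cat(sprintf("<learning_rates> alpha_v = %.4g, alpha_m = %.4g, alpha_cd = %.4g\n",
              x[[1L]], x[[2L]], x[[3L]]))
  invisible(x)
}

as_learning_rates <- function(x) {
  if (inherits(x, "learning_rates")) return(x)
  x <- as.numeric(x)
  learning_rates(x[1L], x[2L], x[3L])
}

# Analytic error gradients dE/d(omega) used by the learner. Pd is treated as
# externally given (not differentiated through the CVE contingency): the
# learner follows its internal estimate of the gradient, and under that
# convention the CTS and CVE gradients coincide.
.error_gradient <- function(wv, wm, wcd, P1, mode) {
  switch(mode,
         prediction  = c(P1 * (wm * (wcd - 1) - 1),
                         P1 * wv * (wcd - 1),
                         P1 * wv * wm),
         postdiction = c(P1 * wm * (wcd - 2),
                         P1 * wv * (wcd - 2),
                         P1 * wv * wm),
         visual      = c(-P1 * wm, -P1 * wv, 0))
}

#' Gradient of the error signal with respect to the gains
#'
#' Returns the learner's internal estimate of \eqn{\partial E/\partial\omega}
#' as a 3-vector (deg per unit gain), evaluated analytically. The imposed
#' displacement `Pd` is held fixed ("clamped") within the trial even in CVE
#' conditions, where it physically depends on the gains: the learner's
#' gradient does not see through the experimental contingency.
#'
#' @inheritParams error_signal
#' @return Numeric 3-vector `(d/d omega_v, d/d omega_m, d/d omega_cd)`.
#' @examples
#' error_gradient(gain_state(), condition_paradigm("CTS_in"), "postdiction")
#' @export
error_gradient <- function(state, paradigm,
                           mode = c("prediction", "postdiction", "visual")) {
  state <- as_gain_state(state)
  mode <- match.arg(mode)
  g <- .error_gradient(state[[1L]], state[[2L]], state[[3L]], paradigm$P1, mode)
  names(g) <- c("omega_v", "omega_m", "omega_cd")
  g
}

#' One delta-rule update of the gain state
#'
#' Applies \eqn{\omega(n+1) = \omega(n) - 2\,\alpha\,E(n)\,
#' \partial E(n)/\partial\omega(n)} componentwise with the diagonal rate
#' matrix, with error and gradient evaluated on the pre-update state.
#'
#' @param state A [gain_state()].
#' @param rates A [learning_rates()] vector.
#' @param paradigm A [paradigm()].
#' @param mode Error mode, see [error_signal()].
#' @return The updated [gain_state()].
#' @examples
#' delta_update(gain_state(), learning_rates(5.2e-6, 3.5e-5, 1.8e-5),
#'              condition_paradigm("CTS_in"), "postdiction")
#' @export
delta_update <- function(state, rates, paradigm,
                         mode = c("prediction", "postdiction", "visual")) {
  state <- as_gain_state(state)
  rates <- as_learning_rates(rates)
  mode <- match.arg(mode)
  cve <- paradigm$kind == "CVE"
  e <- .error_value(state[[1L]], state[[2L]], state[[3L]],
                    paradigm$P1, paradigm$Ps, cve, mode)
  g <- .error_gradient(state[[1L]], state[[2L]], state[[3L]], paradigm$P1, mode)
  w <- unclass(state) - 2 * unclass(rates) * e * g
  gain_state(w[1L], w[2L], w[3L])
}

# Tight scalar recursion used by simulate_learning() and the fit objective.
# Returns list(gains = n x 3 matrix, error = length-n vector, diverged).
# Row i holds the state *before* the update of trial i (trial 1 = initial).
.simulate_core <- function(w, a, P1, Ps, cve, n_trials, mode, cap) {
  gains <- matrix(NA_real_, nrow = n_trials, ncol = 3L)
  err <- numeric(n_trials)
  wv <- w[1L]; wm <- w[2L]; wcd <- w[3L]
  av2 <- 2 * a[1L]; am2 <- 2 * a[2L]; acd2 <- 2 * a[3L]
  diverged <- FALSE
  pred <- mode == "prediction"; post <- mode == "postdiction"
  for (i in seq_len(n_trials)) {
    gains[i, 1L] <- wv; gains[i, 2L] <- wm; gains[i, 3L] <- wcd
    u <- wv * wm
    Pd <- if (cve) P1 * (u - 1) + Ps else Ps
    V2 <- P1 * (1 - u) + Pd
    if (pred) {
      e <- P1 * (1 + wv * (wm * (wcd - 1) - 1)) + Pd
      gv <- P1 * (wm * (wcd - 1) - 1)
      gm <- P1 * wv * (wcd - 1)
      gcd <- P1 * u
    } else if (post) {
      e <- P1 * (1 + u * (wcd - 2)) + Pd
      gv <- P1 * wm * (wcd - 2)
      gm <- P1 * wv * (wcd - 2)
      gcd <- P1 * u
    } else {
      e <- V2
      gv <- -P1 * wm
      gm <- -P1 * wv
      gcd <- 0
    }
    err[i] <- e
    if (i < n_trials) {
      wv <- wv - av2 * e * gv
      wm <- wm - am2 * e * gm
      wcd <- wcd - acd2 * e * gcd
      if (abs(wv) > cap || abs(wm) > cap || abs(wcd) > cap) {
        diverged <- TRUE
        gains[(i + 1L):n_trials, ] <- rep(c(wv, wm, wcd), each = n_trials - i)
        err[(i + 1L):n_trials] <- NA_real_
        break
      }
    }
  }
  list(gains = gains, error = err, diverged = diverged)
}

#' Simulate trial-by-trial learning
#'
#' Iterates the delta rule for `n_trials` trials under a fixed paradigm and
#' records the gain state, all forward-model observables, and the error
#' signal at every trial. Trial 1 holds the initial state before any update;
#' the simulation is deterministic.
#'
#' @inheritParams delta_update
#' @param n_trials Number of trials (>= 1).
#' @param cap Divergence guard: if any |gain| exceeds `cap` the simulation
#'   stops updating. With `divergence = "stop"` (default) this is an error;
#'   with `"flag"` the truncated trajectory is returned with attribute
#'   `diverged = TRUE` (used internally by the fit objective, which converts
#'   it into a large finite penalty).
#' @param divergence `"stop"` or `"flag"`.
#' @return A data frame of class `"trajectory"` with columns `trial`,
#'   `omega_v`, `omega_m`, `omega_cd`, `V1`, `M`, `CDV`, `V2_hat`, `V2`,
#'   `error`, plus attributes `mode`, `paradigm` and `diverged`.
#' @examples
#' tr <- simulate_learning(gain_state(), learning_rates(5e-6, 3.5e-5, 1.8e-5),
#'                         condition_paradigm("CTS_in"), 281, "postdiction")
#' tail(tr$error, 1)  # error largely decayed after 281 trials
#' @export
simulate_learning <- function(state, rates, paradigm, n_trials = 281,
                              mode = c("prediction", "postdiction", "visual"),
                              cap = 10, divergence = c("stop", "flag")) {
  state <- as_gain_state(state)
  rates <- as_learning_rates(rates)
  mode <- match.arg(mode)
  divergence <- match.arg(divergence)
  stopifnot(n_trials >= 1)
  cve <- paradigm$kind == "CVE"
  sim <- .simulate_core(unclass(state), unclass(rates), paradigm$P1,
                        paradigm$Ps, cve, as.integer(n_trials), mode, cap)
  if (sim$diverged && divergence == "stop")
    stop(sprintf("learning diverged (|gain| > %g); reduce the learning rates",
                 cap), call. = FALSE)
  g <- sim$gains
  P1 <- paradigm$P1; Ps <- paradigm$Ps
  V1 <- P1 * g[, 1L]
  M <- V1 * g[, 2L]
  CDV <- M * g[, 3L]
  Pd <- if (cve) P1 * (g[, 1L] * g[, 2L] - 1) + Ps else rep(Ps, nrow(g))
  V2 <- P1 * (1 - g[, 1L] * g[, 2L]) + Pd
  out <- data.frame(trial = seq_len(nrow(g)),
                    omega_v = g[, 1L], omega_m = g[, 2L], omega_cd = g[, 3L],
                    V1 = V1, M = M, CDV = CDV, V2_hat = V1 - CDV, V2 = V2,
                    error = sim$error)
  attr(out, "mode") <- mode
  attr(out, "paradigm") <- paradigm
  attr(out, "diverged") <- sim$diverged
  class(out) <- c("trajectory", "data.frame")
  out
}
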