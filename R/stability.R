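#' Fixed-point plane of the postdiction dynamics
#'
#' Solves the zero-error condition of the postdictive motor error for the
#' motor gain at given visual and CD gains. For CTS conditions
#' \eqn{\omega_m = -(P_1 + P_s)/(P_1 \omega_v (\omega_{cd} - 2))}; for CVE
#' conditions \eqn{\omega_m = -P_s/(P_1 \omega_v (\omega_{cd} - 1))}. Every
#' point of the resulting plane in gain space is a non-isolated fixed point
#' of the learning dynamics.
#'
#' Note the CVE branch degenerates at `Ps = 0` (it returns `omega_m = 0`,
#' the only root of the algebraic condition); the practically relevant
#' baseline fixed set is the CTS branch with `Ps = 0`.
#'
#' @param omega_v,omega_cd Gains at which to evaluate the plane (vectorized).
#' @param paradigm A [paradigm()].
#' @return `omega_m` on the fixed-point plane.
#' @examples
#' fixed_point_omega_m(1, 1, paradigm("BASELINE"))  # identity state
#' @export
fixed_point_omega_m <- function(omega_v, omega_cd, paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  P1 <- paradigm$P1; Ps <- paradigm$Ps
  if (any(omega_v == 0))
    stop("singular slice: omega_v must be nonzero", call. = FALSE)
  if (paradigm$kind == "CVE") {
    if (any(omega_cd == 1))
      stop("singular slice: omega_cd = 1 in a CVE condition", call. = FALSE)
    -Ps / (P1 * omega_v * (omega_cd - 1))
  } else {
    if (any(omega_cd == 2))
      stop("singular slice: omega_cd = 2 in a CTS condition", call. = FALSE)
    -(P1 + Ps) / (P1 * omega_v * (omega_cd - 2))
  }
}

#' Per-trial gain change of the postdiction dynamics
#'
#' The autonomous one-trial change \eqn{\Delta\omega(n) = -2\alpha
#' E_{post}(n)\, \partial E_{post}(n)/\partial\omega(n)}, i.e. the vector
#' field whose fixed points the stability analysis characterizes. Shares its
#' implementation with [delta_update()].
#'
#' @inheritParams delta_update
#' @param mode Error mode; the stability analysis concerns `"postdiction"`.
#' @return Named numeric 3-vector of per-trial gain changes.
#' @export
gain_step <- function(state, rates, paradigm, mode = "postdiction") {
  state <- as_gain_state(state)
  upd <- delta_update(state, rates, paradigm, mode)
  out <- unclass(upd) - unclass(state)
  names(out) <- c("omega_v", "omega_m", "omega_cd")
  out
}

#' Jacobian of the per-trial gain change
#'
#' Analytic Jacobian of \eqn{\Delta\omega = -2\alpha E g} with respect to
#' the gains, by the product rule
#' \eqn{J = -2\,\mathrm{diag}(\alpha)\,(g\,\nabla E^\top + E\,\partial
#' g/\partial\omega)}. By default the error's gradient \eqn{\nabla E} uses
#' the learner's convention (the imposed displacement `Pd` clamped within
#' the trial, so \eqn{\nabla E = g}), consistent with the learning rule;
#' `pd_clamped = FALSE` differentiates fully through the CVE contingency
#' for exploration. A centered finite-difference variant
#' (`numeric = TRUE`) serves as an independent check.
#'
#' @inheritParams gain_step
#' @param pd_clamped Clamp `Pd` in the error gradient (default), matching
#'   the learner's internal gradient.
#' @param numeric Use centered finite differences of [gain_step()] instead
#'   of the analytic form (with `Pd` clamped or not accordingly).
#' @param h Finite-difference step.
#' @return 3x3 matrix, rows/cols ordered (omega_v, omega_m, omega_cd).
#' @export
learning_jacobian <- function(state, rates, paradigm, mode = "postdiction",
                              pd_clamped = TRUE, numeric = FALSE, h = 1e-6) {
  state <- as_gain_state(state)
  rates <- as_learning_rates(rates)
  wv <- state[[1L]]; wm <- state[[2L]]; wcd <- state[[3L]]
  P1 <- paradigm$P1
  cve <- paradigm$kind == "CVE"

  if (numeric) {
    # clamped: evaluate the step under a CTS paradigm whose step equals the
    # current Pd, which freezes Pd while the gains are perturbed
    pfix <- if (pd_clamped && cve) {
      Pd0 <- compute_observables(state, paradigm)[["Pd"]]
      paradigm("CTS", P1, Pd0)
    } else paradigm
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      wp <- unclass(state); wm_ <- unclass(state)
      wp[j] <- wp[j] + h; wm_[j] <- wm_[j] - h
      J[, j] <- (gain_step(gain_state(wp[1], wp[2], wp[3]), rates, pfix, mode) -
                 gain_step(gain_state(wm_[1], wm_[2], wm_[3]), rates, pfix, mode)) /
        (2 * h)
    }
    dimnames(J) <- list(names(unclass(state)), names(unclass(state)))
    return(J)
  }

  e <- error_signal(state, paradigm, mode)
  g <- .error_gradient(wv, wm, wcd, P1, mode)
  # gradient of E as a function of the state: equals g when Pd is clamped;
  # full differentiation adds the Pd(omega) terms of the CVE contingency
  gradE <- if (pd_clamped || !cve) g else g + c(P1 * wm, P1 * wv, 0)
  dg <- switch(mode,
               postdiction = matrix(c(0, P1 * (wcd - 2), P1 * wm,
                                      P1 * (wcd - 2), 0, P1 * wv,
                                      P1 * wm, P1 * wv, 0),
                                    3, 3, byrow = TRUE),
               prediction = matrix(c(0, P1 * (wcd - 1), P1 * wm,
                                     P1 * (wcd - 1), 0, P1 * wv,
                                     P1 * wm, P1 * wv, 0),
                                   3, 3, byrow = TRUE),
               visual = matrix(c(0, -P1, 0,
                                 -P1, 0, 0,
                                 0, 0, 0), 3, 3, byrow = TRUE))
  J <- -2 * diag(unclass(rates)) %*% (outer(g, gradE) + e * dg)
  dimnames(J) <- list(names(unclass(state)), names(unclass(state)))
  J
}

#' Stability classification of a fixed point
#'
#' Eigenvalue-based classification of the 3x3 Jacobian of the per-trial gain
#' change. Because fixed points form a plane (they are non-isolated), zero
#' eigenvalues along the plane are expected and tolerated: the state is
#' labelled `"stable"` if every eigenvalue with |Re| above `tol` has
#' negative real part (attracting transverse to the plane, marginal along
#' it), `"unstable"` if any real part exceeds `tol`, and `"marginal"` if all
#' eigenvalues are (numerically) zero. The trace, determinant and
#' discriminant `tau^2 - 4 det` of the 2x2 sub-Jacobian on the
#' (omega_m, omega_cd) slice at fixed omega_v are also reported, matching
#' the planar vector-field view.
#'
#' @param J 3x3 Jacobian from [learning_jacobian()].
#' @param tol Magnitude below which an eigenvalue real part counts as zero.
#' @return List of class `"stability_report"`: `eigenvalues`, `label`,
#'   `tau`, `det`, `discriminant` (the 2x2 slice quantities), `jacobian`.
#' @export
classify_stability <- function(J, tol = 1e-12) {
  stopifnot(is.matrix(J), all(dim(J) == c(3L, 3L)))
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <- if (any(re > tol)) "unstable"
           else if (all(abs(re) <= tol)) "marginal"
           else "stable"
  J2 <- J[2:3, 2:3]
  structure(list(eigenvalues = ev,
                 label = label,
                 tau = sum(diag(J2)),
                 det = det(J2),
                 discriminant = sum(diag(J2))^2 - 4 * det(J2),
                 jacobian = J),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s\n", x$label))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  cat(sprintf("  (omega_m, omega_cd) slice: tau = %.4g, det = %.4g, tau^2-4det = %.4g\n",
              x$tau, x$det, x$discriminant))
  invisible(x)
}

#' Stability report at a gain state
#'
#' Convenience wrapper: analytic Jacobian at `state` followed by
#' [classify_stability()].
#'
#' @inheritParams learning_jacobian
#' @param tol Zero tolerance for eigenvalue classification.
#' @return A `"stability_report"`.
#' @export
stability_report <- function(state, rates, paradigm, mode = "postdiction",
                             pd_clamped = TRUE, tol = 1e-12) {
  classify_stability(learning_jacobian(state, rates, paradigm, mode,
                                       pd_clamped = pd_clamped), tol = tol)
}

#' Vector field of the learning dynamics on a gain-space slice
#'
#' Evaluates the per-trial gain change on a grid over
#' (omega_m, omega_cd) at fixed omega_v, for plotting the learning flow
#' together with the fixed-point curve; arrows vanish exactly on the curve.
#'
#' @param omega_m,omega_cd Numeric vectors defining the grid.
#' @param omega_v Fixed visual gain of the slice.
#' @inheritParams gain_step
#' @return Data frame with `omega_m`, `omega_cd`, `d_omega_m`, `d_omega_cd`,
#'   `d_omega_v`, `error`.
#' @export
vector_field <- function(omega_m, omega_cd, omega_v, rates, paradigm,
                         mode = "postdiction") {
  grid <- expand.grid(omega_m = omega_m, omega_cd = omega_cd,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  d <- matrix(0, n, 3L)
  e <- numeric(n)
  for (i in seq_len(n)) {
    st <- gain_state(omega_v, grid$omega_m[i], grid$omega_cd[i])
    d[i, ] <- gain_step(st, rates, paradigm, mode)
    e[i] <- error_signal(st, paradigm, mode)
  }
  cbind(grid, data.frame(d_omega_m = d[, 2L], d_omega_cd = d[, 3L],
                         d_omega_v = d[, 1L], error = e))
}
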