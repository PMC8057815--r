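#' Visuomotor gain state
#'
#' Bundle the three learnable gains of the saccadic visuomotor circuit: the
#' visual gain \eqn{\omega_v} (retinal input to perceived target position),
#' the motor gain \eqn{\omega_m} (inverse model: target percept to motor
#' command), and the corollary-discharge gain \eqn{\omega_{cd}} (forward
#' dynamics model: motor command copy to computed displacement of visual
#' space, CDV). All gains are dimensionless scalars; a value of 1 means the
#' corresponding transformation is veridical.
#'
#' @param omega_v Visual gain.
#' @param omega_m Motor gain (inverse model).
#' @param omega_cd Corollary-discharge gain (forward dynamics model).
#' @return A named numeric vector of class `"gain_state"`.
#' @examples
#' gain_state(1, 0.95, 0.98)
#' @export
gain_state <- function(omega_v = 1, omega_m = 1, omega_cd = 1) {
  w <- c(omega_v = as.numeric(omega_v), omega_m = as.numeric(omega_m),
         omega_cd = as.numeric(omega_cd))
  if (length(w) != 3L || !all(is.finite(w)))
    stop("gain state must be three finite numbers", call. = FALSE)
  structure(w, class = "gain_state")
}

#' @export
print.gain_state <- function(x, ...) {
  cat(sprintf("<gain_state> omega_v = %.6g, omega_m = %.6g, omega_cd = %.6g\n",
              x[[1L]], x[[2L]], x[[3L]]))
  invisible(x)
}

as_gain_state <- function(x) {
  if (inherits(x, "gain_state")) return(x)
  x <- as.numeric(x)
  gain_state(x[1L], x[2L], x[3L])
}

#' Double-step paradigm descriptor
#'
#' Describes one learning condition of the intra-saccadic target-step
#' paradigm: the pre-saccadic target eccentricity `P1` and the signed target
#' step `Ps`, both in degrees of visual angle (rightward/outward positive).
#' In a CTS ("constant target step") condition the target steps by `Ps`
#' relative to its pre-saccadic position; in a CVE ("constant visual error")
#' condition it reappears `Ps` away from the saccade landing position, so the
#' retinal error cannot be reduced by learning. `BASELINE` is a CTS condition
#' with `Ps = 0`.
#'
#' @param kind One of `"CTS"`, `"CVE"`, `"BASELINE"`.
#' @param P1 Pre-saccadic target eccentricity (deg), positive.
#' @param Ps Signed intra-saccadic target step (deg); negative = inward.
#' @return An object of class `"paradigm"`.
#' @examples
#' paradigm("CTS", P1 = 13, Ps = -3)  # inward constant target step
#' paradigm("BASELINE")
#' @export
paradigm <- function(kind = c("CTS", "CVE", "BASELINE"), P1 = 13, Ps = -3) {
  kind <- match.arg(kind)
  P1 <- as.numeric(P1)
  if (!is.finite(P1) || P1 <= 0)
    stop("P1 must be a positive eccentricity in degrees", call. = FALSE)
  if (kind == "BASELINE") Ps <- 0
  Ps <- as.numeric(Ps)
  if (!is.finite(Ps)) stop("Ps must be finite", call. = FALSE)
  structure(list(kind = kind, P1 = P1, Ps = Ps), class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("<paradigm> %s: P1 = %g deg, Ps = %+g deg\n", x$kind, x$P1, x$Ps))
  invisible(x)
}

#' Named learning conditions of the study design
#'
#' Convenience constructor for the four learning conditions (and baseline)
#' with the study's constants P1 = 13 deg and |Ps| = 3 deg.
#'
#' @param condition One of `"CTS_in"`, `"CTS_out"`, `"CVE_in"`, `"CVE_out"`,
#'   `"baseline"`.
#' @return A [paradigm()] object.
#' @examples
#' condition_paradigm("CTS_out")
#' @export
condition_paradigm <- function(condition = c("CTS_in", "CTS_out",
                                             "CVE_in", "CVE_out", "baseline")) {
  condition <- match.arg(condition)
  switch(condition,
         CTS_in   = paradigm("CTS", 13, -3),
         CTS_out  = paradigm("CTS", 13, +3),
         CVE_in   = paradigm("CVE", 13, -3),
         CVE_out  = paradigm("CVE", 13, +3),
         baseline = paradigm("BASELINE", 13, 0))
}

# Internal scalar core shared by everything downstream. Deterministic
# (motor noise enters only the synthetic-data generator).
# Returns a named numeric vector of the eight observables.
.observables <- function(wv, wm, wcd, P1, Ps, cve) {
  V1 <- P1 * wv
  M <- V1 * wm
  CDM <- M
  CDV <- CDM * wcd
  V2_hat <- V1 - CDV
  Pd <- if (cve) P1 * (wv * wm - 1) + Ps else Ps
  V2 <- P1 * (1 - wv * wm) + Pd
  V1_hat <- V2 + CDV
  c(V1 = V1, M = M, CDM = CDM, CDV = CDV, V2_hat = V2_hat,
    Pd = Pd, V2 = V2, V1_hat = V1_hat)
}

#' Forward model: observables of one trial
#'
#' Evaluates the noise-free forward model for a gain state under a paradigm,
#' returning all per-trial observables in degrees: perceived pre-saccadic
#' target `V1 = P1 omega_v`; motor command `M = V1 omega_m` (equals the
#' saccade vector); corollary discharge `CDM = M`; computed displacement of
#' visual space `CDV = CDM omega_cd`; predicted post-saccadic retinal target
#' `V2_hat = V1 - CDV`; imposed trans-saccadic displacement `Pd` (`Ps` for
#' CTS/baseline, landing-referenced for CVE); actual post-saccadic retinal
#' target `V2 = P1 (1 - omega_v omega_m) + Pd`; and the postdicted
#' pre-saccadic target `V1_hat = V2 + CDV`.
#'
#' @param state A [gain_state()] (or numeric length-3 vector).
#' @param paradigm A [paradigm()].
#' @return Named numeric vector of class `"observables"`.
#' @examples
#' compute_observables(gain_state(1, 0.9, 1.1), paradigm("CTS", 13, -3))
#' @export
compute_observables <- function(state, paradigm) {
  state <- as_gain_state(state)
  stopifnot(inherits(paradigm, "paradigm"))
  obs <- .observables(state[[1L]], state[[2L]], state[[3L]],
                      paradigm$P1, paradigm$Ps, paradigm$kind == "CVE")
  structure(obs, class = "observables")
}

#' @export
print.observables <- function(x, ...) {
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' Visual prediction error
#'
#' The deviation of the post-saccadic retinal target position from its
#' corollary-discharge based prediction,
#' \eqn{E_{pre} = V_2 - \hat V_2}. Zero when the world appears exactly where
#' the forward outcome model predicted it.
#'
#' @param obs An `observables` vector from [compute_observables()].
#' @return Error in degrees.
#' @export
prediction_error <- function(obs) {
  unname(obs[["V2"]] - obs[["V2_hat"]])
}

#' Postdictive motor error
#'
#' The error of the motor command with respect to the postdicted pre-saccadic
#' target position, \eqn{E_{post} = \hat V_1 - M}: the post-saccadic target is
#' mapped back into pre-saccadic coordinates via CDV (backward outcome model,
#' assuming a stable world) and compared to the executed command.
#'
#' @inheritParams prediction_error
#' @return Error in degrees.
#' @export
postdiction_error <- function(obs) {
  unname(obs[["V1_hat"]] - obs[["M"]])
}

.mode_names <- c("prediction", "postdiction", "visual")

# error for a given mode from raw scalars; "visual" is the plain
# post-saccadic retinal error V2 (comparison mode only)
.error_value <- function(wv, wm, wcd, P1, Ps, cve, mode) {
  obs <- .observables(wv, wm, wcd, P1, Ps, cve)
  switch(mode,
         prediction  = obs[["V2"]] - obs[["V2_hat"]],
         postdiction = obs[["V1_hat"]] - obs[["M"]],
         visual      = obs[["V2"]])
}

#' Error signal of a trial under a learning mode
#'
#' @param state A [gain_state()].
#' @param paradigm A [paradigm()].
#' @param mode `"prediction"` (visual prediction error),
#'   `"postdiction"` (postdictive motor error) or `"visual"` (plain
#'   post-saccadic retinal error, a comparison mode).
#' @return Error in degrees.
#' @examples
#' error_signal(gain_state(), condition_paradigm("CTS_in"), "postdiction")
#' @export
error_signal <- function(state, paradigm,
                         mode = c("prediction", "postdiction", "visual")) {
  state <- as_gain_state(state)
  mode <- match.arg(mode)
  .error_value(state[[1L]], state[[2L]], state[[3L]],
               paradigm$P1, paradigm$Ps, paradigm$kind == "CVE", mode)
}
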