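#' Derive CDV and the visuomotor gains from probe measurements
#'
#' Inverts the forward model on measured probe-block observables: from the
#' median pre-saccadic localization `V1`, saccade vector `M` and
#' post-saccadic localization relative to saccade landing `V2_hat`, it
#' derives `CDV = V1 - V2_hat`, `omega_v = V1/P1`, `omega_m = M/V1` and
#' `omega_cd = CDV/M` (the corollary discharge `CDM` is identified with the
#' measured saccade vector). This is the exact algebraic inverse of
#' [compute_observables()] on those three observables.
#'
#' @param V1,M,V2_hat Measured observables in degrees (vectorized).
#' @param P1 Physical target eccentricity in degrees.
#' @return A data frame with columns `omega_v`, `omega_m`, `omega_cd`, `CDV`.
#' @examples
#' derive_gains(13, 12.4, 0.8, P1 = 13)  # baseline saccade/CDV hypometry
#' @export
derive_gains <- function(V1, M, V2_hat, P1 = 13) {
  V1 <- as.numeric(V1); M <- as.numeric(M); V2_hat <- as.numeric(V2_hat)
  if (any(!is.finite(V1)) || any(!is.finite(M)) || any(!is.finite(V2_hat)))
    stop("probe measurements must be finite", call. = FALSE)
  if (any(V1 == 0) || any(M == 0))
    stop("degenerate probe measurement: V1 and M must be nonzero", call. = FALSE)
  CDV <- V1 - V2_hat
  data.frame(omega_v = V1 / P1, omega_m = M / V1, omega_cd = CDV / M,
             CDV = CDV)
}

#' Probe series of one subject and condition
#'
#' Five probe blocks of measured `(V1, M, V2_hat)` medians, attached to the
#' pure-saccade-trial indices `[1, 71, 141, 211, 281]` and carrying the
#' fitting weights `eta`: 1.52 for the long probe blocks (trials 1 and 281,
#' 21 localizations each) and 0.65 for the short ones (trials 71, 141, 211,
#' 9 localizations each), reflecting the certainty of each block median.
#'
#' @param V1,M,V2_hat Numeric length-5 vectors of block medians (deg),
#'   ordered probe block 1 to 5.
#' @param condition A [paradigm()] or a condition name accepted by
#'   [condition_paradigm()].
#' @param subject Optional subject identifier.
#' @return A data frame of class `"probe_series"` with columns `block`,
#'   `trial`, `V1`, `M`, `V2_hat`, `eta`, and attributes `paradigm` and
#'   `subject`.
#' @export
probe_series <- function(V1, M, V2_hat, condition = "CTS_in", subject = NA) {
  if (length(V1) != 5L || length(M) != 5L || length(V2_hat) != 5L)
    stop("incomplete series: a probe series needs exactly 5 blocks",
         call. = FALSE)
  if (is.character(condition)) condition <- condition_paradigm(condition)
  stopifnot(inherits(condition, "paradigm"))
  out <- data.frame(block = 1:5,
                    trial = c(1L, 71L, 141L, 211L, 281L),
                    V1 = as.numeric(V1), M = as.numeric(M),
                    V2_hat = as.numeric(V2_hat),
                    eta = c(1.52, 0.65, 0.65, 0.65, 1.52))
  attr(out, "paradigm") <- condition
  attr(out, "subject") <- subject
  class(out) <- c("probe_series", "data.frame")
  out
}

#' @export
print.probe_series <- function(x, ...) {
  p <- attr(x, "paradigm")
  cat(sprintf("<probe_series> %s Ps = %+g, subject %s\n", p$kind, p$Ps,
              as.character(attr(x, "subject"))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Gain changes across learning
#'
#' Per-gain change from probe block 1 to probe block 5 (and the change in
#' CDV), the summary used to test which visuomotor gains are plastic.
#'
#' @param series A [probe_series()].
#' @return One-row data frame with `d_omega_v`, `d_omega_m`, `d_omega_cd`,
#'   `d_CDV`.
#' @export
gain_changes <- function(series) {
  stopifnot(inherits(series, "probe_series"))
  if (nrow(series) != 5L)
    stop("incomplete series: 5 probe blocks required", call. = FALSE)
  P1 <- attr(series, "paradigm")$P1
  g <- derive_gains(series$V1, series$M, series$V2_hat, P1)
  data.frame(d_omega_v = g$omega_v[5L] - g$omega_v[1L],
             d_omega_m = g$omega_m[5L] - g$omega_m[1L],
             d_omega_cd = g$omega_cd[5L] - g$omega_cd[1L],
             d_CDV = g$CDV[5L] - g$CDV[1L])
}

#' Cohort t-tests of gain changes against zero
#'
#' Two-sided one-sample t-tests of each per-subject gain change against
#' zero. With `align_direction = TRUE` the changes of inward conditions
#' (`Ps < 0`) are sign-flipped before testing, so that inward and outward
#' cohorts can be pooled or compared on a common learning-direction scale.
#'
#' @param deltas Data frame of per-subject gain changes with columns
#'   `d_omega_v`, `d_omega_m`, `d_omega_cd` (one row per subject), e.g.
#'   stacked rows of [gain_changes()].
#' @param align_direction Flip signs for inward learning before testing.
#' @param Ps Signed target step of the condition; only used when
#'   `align_direction` is `TRUE`.
#' @return Data frame with one row per gain: `gain`, `mean`, `sd`, `t`,
#'   `df`, `p`.
#' @examples
#' d <- data.frame(d_omega_v = c(0.01, -0.02, 0.0),
#'                 d_omega_m = c(0.1, 0.2, 0.3),
#'                 d_omega_cd = c(-0.1, -0.15, -0.05))
#' cohort_gain_tests(d)
#' @export
cohort_gain_tests <- function(deltas, align_direction = FALSE, Ps = -3) {
  cols <- c("d_omega_v", "d_omega_m", "d_omega_cd")
  if (!all(cols %in% names(deltas)))
    stop("deltas must contain d_omega_v, d_omega_m, d_omega_cd", call. = FALSE)
  n <- nrow(deltas)
  if (n < 2L) stop("at least 2 subjects required for a t-test", call. = FALSE)
  sgn <- if (align_direction && Ps < 0) -1 else 1
  out <- lapply(cols, function(cl) {
    x <- sgn * deltas[[cl]]
    if (stats::sd(x) == 0) {
      data.frame(gain = sub("^d_", "", cl), mean = mean(x), sd = 0,
                 t = if (mean(x) == 0) 0 else NA_real_,
                 df = n - 1L, p = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(x, mu = 0, alternative = "two.sided")
      data.frame(gain = sub("^d_", "", cl), mean = mean(x), sd = stats::sd(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}
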