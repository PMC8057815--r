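#' Robust median with scaled-MAD outlier exclusion
#'
#' Median after a single pass of outlier removal: values more than three
#' scaled median absolute deviations from the median are excluded, where the
#' scaled MAD is `1.4826 * median(|x - median(x)|)` (normal-consistency
#' scaling). If the MAD is zero but distinct values exist, only values equal
#' to the median are kept.
#'
#' @param x Numeric vector of at least one finite value (deg).
#' @return The robust median (deg).
#' @examples
#' robust_median(c(10, 11, 12, 13, 14, 50))  # 50 is excluded -> 12
#' @export
robust_median <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("robust_median needs at least one value",
                            call. = FALSE)
  med <- stats::median(x)
  dev <- abs(x - med)
  smad <- 1.4826 * stats::median(dev)
  keep <- if (smad == 0) dev == 0 else dev <= 3 * smad
  stats::median(x[keep])
}

# acceptance rules per trial type, in attribution order:
# latency -> amplitude -> flash-timing -> fixation-hold -> click-region
.rule_order <- c("latency", "amplitude", "flash_timing", "fixation_hold",
                 "click_region")

.failed_rules <- function(tr) {
  type <- tr$trial_type
  fails <- character(0)
  if (type %in% c("saccade", "refresh", "post_loc")) {
    if (is.na(tr$latency) || tr$latency < 100 || tr$latency > 400)
      fails <- c(fails, "latency")
    if (is.na(tr$saccade_vector) || tr$saccade_vector < 5)
      fails <- c(fails, "amplitude")
  }
  if (type == "post_loc") {
    if (is.na(tr$flash_to_saccade) || tr$flash_to_saccade < 100)
      fails <- c(fails, "flash_timing")
    if (is.na(tr$held_landing) || !tr$held_landing ||
        (!is.na(tr$fixation_break_ms) && tr$fixation_break_ms > 1400))
      fails <- c(fails, "fixation_hold")
    if (is.na(tr$click_y_fraction) || tr$click_y_fraction <= 0.30)
      fails <- c(fails, "click_region")
  }
  if (type == "pre_loc") {
    if (is.na(tr$saccade_within_400ms) || tr$saccade_within_400ms)
      fails <- c(fails, "flash_timing")
    if (!is.na(tr$fixation_break_ms) && tr$fixation_break_ms > 1400)
      fails <- c(fails, "fixation_hold")
    if (is.na(tr$click_y_fraction) || tr$click_y_fraction <= 0.30)
      fails <- c(fails, "click_region")
  }
  fails
}

#' Apply the trial-acceptance filters
#'
#' Keeps saccade-bearing trials (saccade, refresh, post-saccadic
#' localization) only if the primary saccade had a latency between 100 and
#' 400 ms and a horizontal vector of at least 5 deg. Post-saccadic
#' localizations additionally require the saccade to start no earlier than
#' 100 ms after flash offset (avoiding peri-saccadic compression), gaze held
#' at the landing position with at most 1400 ms of fixation break, and a
#' click above the lower 30% of the display. Pre-saccadic localizations
#' require no saccade within 400 ms of flash onset, the same fixation-hold
#' limit, and the same click-region rule.
#'
#' Rejected trials are attributed to the first failed rule in the order
#' latency, amplitude, flash timing, fixation hold, click region; a trial
#' may fail several rules, so per-rule failure counts can exceed the number
#' of rejected trials.
#'
#' @param trials Data frame of trial records; see [simulate_subject()] for
#'   the column schema.
#' @return List with `accepted` (filtered data frame), `rejected` (named
#'   counts by attributed rule), `failures` (named counts of every rule
#'   failure), and `n_total`.
#' @export
filter_trials <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  known <- c("saccade", "refresh", "pre_loc", "post_loc")
  if (!all(trials$trial_type %in% known))
    stop("malformed input: unknown trial_type ",
         paste(setdiff(unique(trials$trial_type), known), collapse = ", "),
         call. = FALSE)
  needed <- c("latency", "saccade_vector", "flash_to_saccade",
              "click_y_fraction", "fixation_break_ms", "saccade_within_400ms",
              "held_landing")
  for (cl in needed) if (is.null(trials[[cl]])) trials[[cl]] <- NA
  fails <- lapply(seq_len(nrow(trials)), function(i) .failed_rules(trials[i, ]))
  ok <- lengths(fails) == 0L
  attributed <- vapply(fails[!ok], function(f) f[[1L]], character(1))
  rejected <- table(factor(attributed, levels = .rule_order))
  failures <- table(factor(unlist(fails), levels = .rule_order))
  list(accepted = trials[ok, , drop = FALSE],
       rejected = c(rejected),
       failures = c(failures),
       n_total = nrow(trials))
}

#' Probe-block summary of a session
#'
#' Applies the trial filters and reduces each of the five probe blocks to
#' its robust medians: `V1` from the pre-saccadic localization clicks, `M`
#' from the saccade vectors of the post-saccadic localization trials, and
#' `V2_hat` from the post-saccadic clicks re-expressed relative to the
#' saccade landing position (click minus the trial's saccade vector; the
#' saccade starts at fixation, so the vector is the fixation-to-landing
#' distance). Medians use [robust_median()] (3 scaled MADs, single pass).
#'
#' @param trials Trial table of one session (one subject, one condition),
#'   with a `probe_block` column in 1..5 for probe-block trials.
#' @param condition A [paradigm()] or condition name; defaults to the
#'   session's `condition` column if present.
#' @param filtered Set `TRUE` if `trials` has already been filtered.
#' @return A [probe_series()] with an additional attribute `counts`: per
#'   block, the number of accepted pre- and post-saccadic localizations.
#' @export
probe_summary <- function(trials, condition = NULL, filtered = FALSE) {
  if (is.null(condition)) {
    if (is.null(trials$condition))
      stop("supply a condition or a condition column", call. = FALSE)
    condition <- trials$condition[[1L]]
  }
  if (is.character(condition)) condition <- condition_paradigm(condition)
  if (!filtered) trials <- filter_trials(trials)$accepted
  probes <- trials[!is.na(trials$probe_block), , drop = FALSE]
  V1 <- M <- V2_hat <- numeric(5)
  n_pre <- n_post <- integer(5)
  for (b in 1:5) {
    pre <- probes[probes$probe_block == b & probes$trial_type == "pre_loc", ]
    post <- probes[probes$probe_block == b & probes$trial_type == "post_loc", ]
    if (nrow(pre) == 0L || nrow(post) == 0L)
      stop(sprintf("incomplete block: probe block %d has no accepted %s trials",
                   b, if (nrow(pre) == 0L) "pre-saccadic" else "post-saccadic"),
           call. = FALSE)
    V1[b] <- robust_median(pre$click_x)
    M[b] <- robust_median(post$saccade_vector)
    V2_hat[b] <- robust_median(post$click_x - post$saccade_vector)
    n_pre[b] <- nrow(pre); n_post[b] <- nrow(post)
  }
  out <- probe_series(V1, M, V2_hat, condition,
                      subject = if (!is.null(trials$subject))
                        trials$subject[[1L]] else NA)
  attr(out, "counts") <- data.frame(block = 1:5, n_pre = n_pre, n_post = n_post)
  out
}
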