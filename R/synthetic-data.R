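#' Session schedule of the probe/learning design
#'
#' The deterministic nine-block session: odd blocks probe the system state
#' (repeats of pre-saccadic localization, refresh saccade, post-saccadic
#' localization, refresh saccade, with the final refresh dropped: 21 repeats
#' in blocks 1 and 9 giving 4*21-1 = 83 trials, 9 repeats in blocks 3, 5, 7
#' giving 4*9-1 = 35 trials), and even blocks are 70 learning saccade trials
#' each; 4*70 + 2*83 + 3*35 = 551 trials in total. Two trial counters are
#' maintained: the schedule position and the pure-saccade-trial axis `n` on
#' which learning-block trials advance and the five probe blocks sit at
#' `n = 1, 71, 141, 211, 281`.
#'
#' @return Data frame with columns `trial`, `block`, `block_type`
#'   (`"probe"`/`"learning"`), `probe_block` (1..5 or `NA`), `trial_type`
#'   (`"pre_loc"`, `"refresh"`, `"post_loc"`, `"saccade"`), and
#'   `pure_trial` (the model's trial axis: the pure-trial index at which a
#'   probe block measures the state, or the index advanced by each learning
#'   trial).
#' @examples
#' nrow(make_schedule())  # 551
#' @export
make_schedule <- function() {
  probe_block_trials <- function(n_rep) {
    tt <- rep(c("pre_loc", "refresh", "post_loc", "refresh"), n_rep)
    tt[-length(tt)]  # last refresh dropped
  }
  rows <- list()
  probe_idx <- 0L
  pure <- 0L  # pure saccade trials completed so far
  for (block in 1:9) {
    if (block %% 2L == 1L) {
      probe_idx <- probe_idx + 1L
      tt <- probe_block_trials(if (block %in% c(1L, 9L)) 21L else 9L)
      rows[[block]] <- data.frame(block = block, block_type = "probe",
                                  probe_block = probe_idx, trial_type = tt,
                                  pure_trial = pure + 1L)
    } else {
      tt <- rep("saccade", 70L)
      rows[[block]] <- data.frame(block = block, block_type = "learning",
                                  probe_block = NA_integer_, trial_type = tt,
                                  pure_trial = pure + seq_len(70L))
      pure <- pure + 70L
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Default fitted-scale learning rates per condition
#'
#' Condition-specific default learning rates for the synthetic generator,
#' at the scale recovered from human postdiction-model fits (motor rate
#' largest, CD rate intermediate, visual rate smallest).
#'
#' @param condition Condition name, see [condition_paradigm()].
#' @return A [learning_rates()] vector.
#' @export
default_rates <- function(condition = c("CTS_in", "CTS_out",
                                        "CVE_in", "CVE_out", "baseline")) {
  condition <- match.arg(condition)
  switch(condition,
         CTS_in   = learning_rates(5.2e-6, 3.5e-5, 1.8e-5),
         CVE_in   = learning_rates(1.9e-6, 1.3e-5, 5.4e-6),
         CTS_out  = learning_rates(8.4e-8, 1.5e-5, 6.3e-6),
         CVE_out  = learning_rates(2.0e-6, 9.9e-6, 8.0e-6),
         baseline = learning_rates(2e-6, 2e-5, 1e-5))
}

#' Default baseline gain state
#'
#' Baseline gains of a synthetic subject: visual gain 1, motor gain 0.95
#' (the typical ~5% saccadic undershoot), and the CD gain placed on the
#' baseline fixed-point plane of the postdiction dynamics
#' (`omega_cd = 2 - 1/(omega_v omega_m)`), so that the postdictive motor
#' error is nullified before learning - the baseline steady state. This
#' gives a slightly hypometric CDV, as observed.
#'
#' @param omega_v,omega_m Baseline visual and motor gain.
#' @return A [gain_state()] on the baseline plane.
#' @export
baseline_gain_state <- function(omega_v = 1, omega_m = 0.95) {
  gain_state(omega_v, omega_m, 2 - 1 / (omega_v * omega_m))
}

#' Synthetic subject specification
#'
#' Everything needed to generate one reproducible synthetic session:
#' baseline gains, generating learning rates, error mode of the generative
#' learner (postdiction by default, matching the retained model), trial
#' noise, and per-rule filter-violation probabilities. The default
#' violation probabilities are set so that acceptance rates land near the
#' empirically typical ~89% (pre-saccadic localizations) and ~77%
#' (post-saccadic localizations).
#'
#' @param condition Condition name.
#' @param baseline_gains A [gain_state()]; default [baseline_gain_state()].
#' @param rates Generating [learning_rates()]; default [default_rates()] for
#'   the condition.
#' @param mode Generative error mode.
#' @param sigma_motor SD (deg) of motor noise added to measured saccade
#'   vectors.
#' @param sigma_report SD (deg) of localization-click noise.
#' @param violation Named list of per-rule violation probabilities:
#'   `latency`, `amplitude`, `flash`, `held`, `fix_break`, `click_low`,
#'   `pre_saccade` (pre-saccadic localization spoiled by a saccade).
#' @param probe_learning Should the gain state keep learning on the
#'   saccade-bearing trials inside probe blocks? Default `FALSE`: probe
#'   blocks are treated as state-preserving measurements (no systematic
#'   change within a probe block), which keeps the generator aligned with
#'   the fitted model's pure-trial axis.
#' @param seed Integer seed for the subject's random stream.
#' @return List of class `"subject_spec"`.
#' @export
subject_spec <- function(condition = "CTS_in",
                         baseline_gains = baseline_gain_state(),
                         rates = default_rates(condition),
                         mode = "postdiction",
                         sigma_motor = 0.5, sigma_report = 0.5,
                         violation = list(), probe_learning = FALSE,
                         seed = 1L) {
  stopifnot(sigma_motor >= 0, sigma_report >= 0)
  v <- list(latency = 0.06, amplitude = 0.03, flash = 0.05, held = 0.06,
            fix_break = 0.03, click_low = 0.04, pre_saccade = 0.04)
  v[names(violation)] <- violation
  structure(list(condition = condition,
                 baseline_gains = as_gain_state(baseline_gains),
                 rates = as_learning_rates(rates), mode = mode,
                 sigma_motor = sigma_motor, sigma_report = sigma_report,
                 violation = v, probe_learning = isTRUE(probe_learning),
                 seed = as.integer(seed)),
            class = "subject_spec")
}

# draw a latency (ms), valid unless violated
.draw_latency <- function(p_bad) {
  if (stats::runif(1) < p_bad) {
    if (stats::runif(1) < 0.5) stats::runif(1, 40, 95) else stats::runif(1, 410, 600)
  } else {
    min(max(stats::rnorm(1, 219, 24), 105), 395)
  }
}

#' Simulate one synthetic session at trial level
#'
#' Walks the [make_schedule()] trial list with a delta-rule learner.
#' Probe block 1 runs without a target step (baseline); the condition's step
#' applies from block 2 onward. The gain state advances on every learning
#' saccade trial (and, if `probe_learning`, on the saccade-bearing probe
#' trials too). Measured saccade vectors get Gaussian motor noise, clicks
#' get Gaussian report noise, and latencies, click heights and fixation
#' flags are drawn so that a configurable fraction of trials violates each
#' acceptance rule. The learning state itself evolves noise free: only
#' probe-block medians are fitted downstream, where independent trial noise
#' averages out.
#'
#' @param spec A [subject_spec()].
#' @param subject Subject label stored in the table.
#' @return Trial-level data frame (one row per schedule trial) with the
#'   column schema consumed by [filter_trials()] and [probe_summary()]:
#'   `subject`, `condition`, `trial`, `block`, `block_type`, `probe_block`,
#'   `trial_type`, `pure_trial`, `latency`, `saccade_vector`,
#'   `flash_to_saccade`, `click_x`, `click_y_fraction`,
#'   `fixation_break_ms`, `saccade_within_400ms`, `held_landing`.
#' @export
simulate_subject <- function(spec, subject = "s01") {
  stopifnot(inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  sched <- make_schedule()
  pg <- condition_paradigm(spec$condition)
  base <- condition_paradigm("baseline")
  v <- spec$violation
  n <- nrow(sched)
  w <- spec$baseline_gains

  latency <- saccade_vector <- flash_to_saccade <- click_x <- numeric(n)
  click_y <- fix_break <- numeric(n)
  sacc400 <- held <- logical(n)
  latency[] <- NA; saccade_vector[] <- NA; flash_to_saccade[] <- NA
  click_x[] <- NA; click_y[] <- NA; fix_break[] <- NA
  sacc400[] <- NA; held[] <- NA

  for (i in seq_len(n)) {
    in_probe <- sched$block_type[i] == "probe"
    p <- if (in_probe && sched$block[i] == 1L) base else pg
    obs <- compute_observables(w, p)
    type <- sched$trial_type[i]

    if (type == "pre_loc") {
      sacc400[i] <- stats::runif(1) < v$pre_saccade
      click_x[i] <- obs[["V1"]] + stats::rnorm(1, 0, spec$sigma_report)
      click_y[i] <- if (stats::runif(1) < v$click_low)
        stats::runif(1, 0.05, 0.30) else stats::runif(1, 0.35, 0.90)
      fix_break[i] <- if (stats::runif(1) < v$fix_break)
        stats::runif(1, 1450, 3000) else stats::runif(1, 0, 1200)
    } else {
      latency[i] <- .draw_latency(v$latency)
      eps_m <- stats::rnorm(1, 0, spec$sigma_motor)
      vec <- obs[["M"]] + eps_m
      if (stats::runif(1) < v$amplitude) vec <- stats::runif(1, 2, 4.9)
      saccade_vector[i] <- vec
      if (type == "post_loc") {
        flash_to_saccade[i] <- if (stats::runif(1) < v$flash)
          stats::runif(1, 20, 95) else stats::runif(1, 105, 320)
        held[i] <- stats::runif(1) > v$held
        # click is screen-referenced: landing (the measured vector) plus the
        # perceived flash position relative to landing, plus report noise
        click_x[i] <- vec + obs[["V2_hat"]] + stats::rnorm(1, 0, spec$sigma_report)
        click_y[i] <- if (stats::runif(1) < v$click_low)
          stats::runif(1, 0.05, 0.30) else stats::runif(1, 0.35, 0.90)
        fix_break[i] <- if (stats::runif(1) < v$fix_break)
          stats::runif(1, 1450, 3000) else stats::runif(1, 0, 1200)
      }
      update <- !in_probe || spec$probe_learning
      if (update) w <- delta_update(w, spec$rates, p, spec$mode)
    }
  }

  out <- cbind(data.frame(subject = subject, condition = spec$condition),
               sched,
               data.frame(latency = latency, saccade_vector = saccade_vector,
                          flash_to_saccade = flash_to_saccade,
                          click_x = click_x, click_y_fraction = click_y,
                          fixation_break_ms = fix_break,
                          saccade_within_400ms = sacc400,
                          held_landing = held))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject baseline gains and generating rates from the cohort
#' distribution and simulates each subject independently. Baseline visual
#' and motor gains are Gaussian around their defaults, with the CD gain
#' placed on the baseline fixed-point plane (subjects start at steady
#' state); generating rates are log-uniform within `rate_range` times the
#' condition's default rates. Subject seeds are drawn reproducibly from
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param condition Condition name.
#' @param master_seed Integer master seed.
#' @param sigma_motor,sigma_report Trial noise SDs (deg), passed to each
#'   subject.
#' @param gain_sd SDs of the baseline visual and motor gains
#'   (length-2 numeric).
#' @param rate_range Multiplicative log-uniform range around the default
#'   rates; use `c(1, 1)` for identical rates. The default `c(0.7, 1.4)`
#'   yields between-subject spreads of the block-1-to-5 saccade-vector
#'   change comparable to those reported for human cohorts (a few tenths of
#'   a degree to ~1 deg SD) while keeping every subject's saccade inside
#'   the measurable (>= 5 deg) range.
#' @param mode Generative error mode.
#' @param ... Further arguments passed to [subject_spec()] (e.g.
#'   `violation`, `probe_learning`).
#' @return List with `tables` (list of trial tables), `specs` (list of
#'   [subject_spec()]s) and `subjects` (labels).
#' @export
simulate_cohort <- function(n_subjects = 17L, condition = "CTS_in",
                            master_seed = 1L, sigma_motor = 0.5,
                            sigma_report = 0.5, gain_sd = c(0.02, 0.03),
                            rate_range = c(0.7, 1.4), mode = "postdiction",
                            ...) {
  stopifnot(n_subjects >= 1L)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(1e8L, n_subjects)
  wv <- stats::rnorm(n_subjects, 1, gain_sd[1L])
  wm <- stats::rnorm(n_subjects, 0.95, gain_sd[2L])
  a0 <- unclass(default_rates(condition))
  lr <- log(rate_range)
  amat <- vapply(seq_len(n_subjects), function(i)
    a0 * exp(stats::runif(3L, lr[1L], lr[2L])), numeric(3L))
  labels <- sprintf("s%02d", seq_len(n_subjects))
  specs <- lapply(seq_len(n_subjects), function(i)
    subject_spec(condition = condition,
                 baseline_gains = baseline_gain_state(wv[i], wm[i]),
                 rates = learning_rates(amat[1L, i], amat[2L, i], amat[3L, i]),
                 mode = mode, sigma_motor = sigma_motor,
                 sigma_report = sigma_report, seed = seeds[i], ...))
  tables <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(specs[[i]], subject = labels[i]))
  list(tables = tables, specs = specs, subjects = labels)
}

#' Noise-free probe series generated by the model itself
#'
#' Simulates 281 pure trials of learning and reads off the probe-block
#' observables at trials `[1, 71, 141, 211, 281]`, i.e. a probe series with
#' no measurement layer at all. This is the parameter-recovery fixture: a
#' fit to this series must recover the generating rates with essentially
#' zero residual.
#'
#' @param state0 Initial [gain_state()].
#' @param rates Generating [learning_rates()].
#' @param condition Condition name or [paradigm()].
#' @param mode Generative error mode.
#' @return A [probe_series()].
#' @export
simulate_probe_series <- function(state0, rates, condition = "CTS_in",
                                  mode = "postdiction") {
  p <- if (is.character(condition)) condition_paradigm(condition) else condition
  traj <- simulate_learning(state0, rates, p, 281L, mode)
  idx <- c(1L, 71L, 141L, 211L, 281L)
  probe_series(traj$V1[idx], traj$M[idx], traj$V2_hat[idx], p)
}
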