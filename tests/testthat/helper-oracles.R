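# Independent oracles and small fixture builders shared across tests.
# The polynomial forms below are written out independently of the package's
# recursive/compositional implementation, so agreement is a real check.

# expanded closed forms of the observables and errors, with Pd given
poly_v1 <- function(wv, wm, wcd, P1) P1 * wv
poly_m <- function(wv, wm, wcd, P1) P1 * wv * wm
poly_cdv <- function(wv, wm, wcd, P1) P1 * wv * wm * wcd
poly_v2hat <- function(wv, wm, wcd, P1) P1 * wv * (1 - wm * wcd)
poly_v2 <- function(wv, wm, wcd, P1, Pd) P1 * (1 - wv * wm) + Pd
poly_v1hat <- function(wv, wm, wcd, P1, Pd)
  P1 * (1 + wv * wm * (wcd - 1)) + Pd
poly_epre <- function(wv, wm, wcd, P1, Pd)
  P1 * (1 + wv * (wm * (wcd - 1) - 1)) + Pd
poly_epost <- function(wv, wm, wcd, P1, Pd)
  P1 * (1 + wv * wm * (wcd - 2)) + Pd
poly_pd <- function(wv, wm, wcd, P1, Ps, cve)
  if (cve) P1 * (wv * wm - 1) + Ps else Ps

# random gain states in a physiologically wide band, fixed seed per call site
rand_states <- function(n, seed = 42) {
  set.seed(seed)
  cbind(runif(n, 0.5, 1.5),    # omega_v
        runif(n, 0.5, 1.5),    # omega_m
        runif(n, 0.1, 1.9))    # omega_cd
}

# centered finite-difference gradient of the error with Pd clamped at its
# value for the unperturbed state (clamping a CVE condition = evaluating a
# CTS condition whose step equals the current Pd)
fd_error_gradient <- function(state, prdm, mode, h = 1e-6) {
  w0 <- as.numeric(unclass(state))
  Pd0 <- compute_observables(gain_state(w0[1], w0[2], w0[3]), prdm)[["Pd"]]
  pfix <- paradigm("CTS", prdm$P1, Pd0)
  g <- numeric(3)
  for (j in 1:3) {
    wp <- w0; wm_ <- w0
    wp[j] <- wp[j] + h; wm_[j] <- wm_[j] - h
    g[j] <- (error_signal(gain_state(wp[1], wp[2], wp[3]), pfix, mode) -
             error_signal(gain_state(wm_[1], wm_[2], wm_[3]), pfix, mode)) /
      (2 * h)
  }
  g
}

# one trial record of each type with all-valid defaults; override fields
make_trial <- function(trial_type, probe_block = 1L, ...) {
  rec <- data.frame(subject = "s01", condition = "CTS_in", trial = 1L,
                    block = 1L, block_type = "probe",
                    probe_block = probe_block, trial_type = trial_type,
                    pure_trial = 1L,
                    latency = 200, saccade_vector = 12.4,
                    flash_to_saccade = 150, click_x = 13,
                    click_y_fraction = 0.5, fixation_break_ms = 500,
                    saccade_within_400ms = FALSE, held_landing = TRUE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_trials <- function(...) do.call(rbind, list(...))

# a noise-free subject spec with no filter violations
clean_spec <- function(condition = "CTS_in", rates = default_rates(condition),
                       gains = baseline_gain_state(), seed = 1L, ...) {
  subject_spec(condition = condition, baseline_gains = gains, rates = rates,
               sigma_motor = 0, sigma_report = 0,
               violation = list(latency = 0, amplitude = 0, flash = 0,
                                held = 0, fix_break = 0, click_low = 0,
                                pre_saccade = 0),
               seed = seed, ...)
}
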