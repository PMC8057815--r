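#' Read probe series from a CSV file
#'
#' Reads a probe-series table (one row per subject, condition and probe
#' block) and splits it into validated [probe_series()] objects. The
#' canonical header is `subject, condition, block, V1, M, V2hat`; deviating
#' layouts (e.g. a deposited data set with different column names) are
#' adapted through `mapping`, a named character vector from canonical to
#' actual column names, without code changes.
#'
#' @param path CSV file path.
#' @param mapping Named character vector, e.g.
#'   `c(V1 = "preloc_deg", M = "vector_deg", V2hat = "postloc_rel_deg")`.
#'   Unmentioned columns keep their canonical names.
#' @param P1 Target eccentricity (deg) used for the paradigms.
#' @return Named list of [probe_series()], one per subject x condition,
#'   names `"<subject>.<condition>"`.
#' @export
read_probe_series <- function(path, mapping = NULL, P1 = 13) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("subject", "condition", "block", "V1", "M", "V2hat")
  cols <- stats::setNames(canon, canon)
  if (!is.null(mapping)) cols[names(mapping)] <- mapping
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  df <- data.frame(subject = raw[[cols[["subject"]]]],
                   condition = raw[[cols[["condition"]]]],
                   block = raw[[cols[["block"]]]],
                   V1 = as.numeric(raw[[cols[["V1"]]]]),
                   M = as.numeric(raw[[cols[["M"]]]]),
                   V2hat = as.numeric(raw[[cols[["V2hat"]]]]))
  if (any(!is.finite(df$V1)) || any(!is.finite(df$M)) || any(!is.finite(df$V2hat)))
    stop("non-numeric probe values", call. = FALSE)
  if (any(abs(df[c("V1", "M", "V2hat")]) >= 40))
    stop("implausible magnitude (>= 40 deg); are the units degrees?",
         call. = FALSE)
  out <- list()
  for (key in unique(paste(df$subject, df$condition, sep = "."))) {
    sub <- df[paste(df$subject, df$condition, sep = ".") == key, ]
    sub <- sub[order(sub$block), ]
    if (nrow(sub) != 5L || !identical(as.integer(sub$block), 1:5))
      stop("incomplete series for ", key, ": need blocks 1..5", call. = FALSE)
    out[[key]] <- probe_series(sub$V1, sub$M, sub$V2hat,
                               condition_paradigm(sub$condition[[1L]]),
                               subject = sub$subject[[1L]])
  }
  out
}

#' Write probe series to CSV
#'
#' Inverse of [read_probe_series()] (canonical column names).
#'
#' @param series A [probe_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probe_series <- function(series, path) {
  if (inherits(series, "probe_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    p <- attr(s, "paradigm")
    cond <- if (p$kind == "BASELINE") "baseline"
            else paste0(p$kind, if (p$Ps < 0) "_in" else "_out")
    data.frame(subject = as.character(attr(s, "subject")), condition = cond,
               block = s$block, V1 = s$V1, M = s$M, V2hat = s$V2_hat)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as a tidy CSV
#'
#' One row per trial with the gain state, observables, error, error mode
#' and condition label.
#'
#' @param trajectory A `"trajectory"` from [simulate_learning()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  p <- attr(trajectory, "paradigm")
  df <- as.data.frame(trajectory)
  df$mode <- attr(trajectory, "mode")
  df$paradigm <- sprintf("%s(P1=%g,Ps=%+g)", p$kind, p$P1, p$Ps)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `"saccade_fit"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "saccade_fit"))
  p <- attr(fit$series, "paradigm")
  jsonlite::write_json(
    list(mode = fit$mode,
         condition = list(kind = p$kind, P1 = p$P1, Ps = p$Ps),
         alpha = as.list(unclass(fit$alpha)),
         sse = fit$sse, rse = fit$rse,
         initial_state = as.list(unclass(fit$initial_state)),
         metrics = as.list(fit$metrics),
         convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a cohort, applies the trial filters, reduces sessions to
#' probe-block medians, derives the gains and their changes, fits both the
#' prediction- and the postdiction-mode model to every subject, compares the
#' models by paired RSE t-test, and reports the stability classification at
#' each subject's fitted end state. Fully reproducible from
#' `(arguments, seed)`.
#'
#' @param condition Condition name.
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param sigma_motor,sigma_report Trial noise SDs (deg).
#' @param config A [fit_config()].
#' @param out_dir Optional directory: if given, probe series, per-subject
#'   fit JSONs and the gain-change table are written there.
#' @param ... Passed to [simulate_cohort()].
#' @return List with `series`, `gains` (per-subject block gains),
#'   `deltas` (gain changes), `gain_tests`, `fits_prediction`,
#'   `fits_postdiction`, `comparison`, `stability`, `acceptance`
#'   (per-subject filter acceptance fractions).
#' @export
run_pipeline <- function(condition = "CTS_in", n_subjects = 8L, seed = 1L,
                         sigma_motor = 0.5, sigma_report = 0.5,
                         config = fit_config(), out_dir = NULL, ...) {
  coh <- simulate_cohort(n_subjects, condition, master_seed = seed,
                         sigma_motor = sigma_motor,
                         sigma_report = sigma_report, ...)
  p <- condition_paradigm(condition)
  series <- list(); acceptance <- list(); gains <- list(); deltas <- list()
  for (i in seq_along(coh$tables)) {
    flt <- filter_trials(coh$tables[[i]])
    series[[i]] <- probe_summary(flt$accepted, condition, filtered = TRUE)
    acceptance[[i]] <- 1 - sum(flt$rejected) / flt$n_total
    gains[[i]] <- cbind(subject = coh$subjects[i], block = 1:5,
                        derive_gains(series[[i]]$V1, series[[i]]$M,
                                     series[[i]]$V2_hat, p$P1))
    deltas[[i]] <- gain_changes(series[[i]])
  }
  deltas <- do.call(rbind, deltas)
  fits_pre <- lapply(series, fit_learning_rates, mode = "prediction",
                     config = config)
  fits_post <- lapply(series, fit_learning_rates, mode = "postdiction",
                      config = config)
  # stability at the fixed point the fitted trajectory is heading to: insert
  # the fixed-point equation for omega_m at the final (omega_v, omega_cd)
  stab <- lapply(fits_post, function(f) {
    tr <- f$trajectory
    n <- nrow(tr)
    wm_fp <- fixed_point_omega_m(tr$omega_v[n], tr$omega_cd[n], p)
    stability_report(gain_state(tr$omega_v[n], wm_fp, tr$omega_cd[n]),
                     f$alpha, p)
  })
  res <- list(series = series,
              gains = do.call(rbind, gains),
              deltas = deltas,
              gain_tests = cohort_gain_tests(deltas),
              fits_prediction = fits_pre,
              fits_postdiction = fits_post,
              comparison = compare_models(fits_pre, fits_post),
              stability = stab,
              acceptance = unlist(acceptance))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(series))
      attr(series[[i]], "subject") <- coh$subjects[i]
    write_probe_series(series, file.path(out_dir, "probe_series.csv"))
    utils::write.csv(cbind(subject = coh$subjects, deltas),
                     file.path(out_dir, "gain_changes.csv"), row.names = FALSE)
    for (i in seq_along(fits_post))
      write_fit_json(fits_post[[i]],
                     file.path(out_dir, sprintf("fit_postdiction_%s.json",
                                                coh$subjects[i])))
  }
  res
}
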