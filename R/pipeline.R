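#' Simulate the task and run the observer for every subject
#'
#' Convenience wrapper: generates all sequences via [simulate_task()],
#' runs [run_observer()] on each session, and stacks the per-subject
#' traces.
#'
#' @param config a [task_config()].
#' @param ... passed to [run_observer()] (e.g. `kl_direction`).
#' @return list with `subject_traces` (one stacked data.frame per
#'   subject, with a `session` column) and `task` (the raw
#'   [simulate_task()] output).
#' @export
simulate_observer_cohort <- function(config, ...) {
  task <- simulate_task(config)
  subject_traces <- lapply(task, function(subject) {
    stack_subject_trace(lapply(subject, function(cell) {
      run_observer(cell$sequence, config, ...)
    }))
  })
  list(subject_traces = subject_traces, task = task)
}

#' Behavioral battery: the model-side regression results
#'
#' Simulates the full cohort, runs the ideal observer, and computes the
#' model-internal statistics: the pooled update regression (Pearson
#' correlation between the KL belief update and its additive
#' surprise + confidence fit, with and without interaction) and the
#' per-subject confidence regression battery
#' ([confidence_regressions()]), under both outcome-standardization
#' conventions.
#'
#' @param config a [task_config()].
#' @param ... passed to [run_observer()].
#' @return list of class `behavioral_battery` with `update_rho`,
#'   `update_rho_interaction`, `confidence` (z-scored outcome),
#'   `confidence_raw_outcome`, `n_trials_pooled` and `config`.
#' @export
run_behavioral_battery <- function(config, ...) {
  cohort <- simulate_observer_cohort(config, ...)
  traces <- cohort$subject_traces
  # a degenerate scale (too few trials or subjects) is reported, not fatal
  softly <- function(expr) tryCatch(expr, error = function(e) {
    warning("underpowered configuration: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  upd <- softly(update_regression_r(traces, include_interaction = FALSE))
  upd_int <- softly(update_regression_r(traces, include_interaction = TRUE))
  conf_z <- softly(confidence_regressions(traces, zscore_outcome = TRUE))
  conf_raw <- softly(confidence_regressions(traces, zscore_outcome = FALSE))
  structure(
    list(
      update_rho = if (is.null(upd)) NA_real_ else upd$rho,
      update_rho_interaction = if (is.null(upd_int)) NA_real_ else upd_int$rho,
      confidence = conf_z,
      confidence_raw_outcome = conf_raw,
      n_trials_pooled = if (is.null(upd)) 0L else upd$n,
      underpowered = is.null(upd) || is.null(conf_z),
      config = config
    ),
    class = "behavioral_battery"
  )
}

#' @export
print.behavioral_battery <- function(x, ...) {
  cat("Behavioral battery (Bayes-optimal observer)\n")
  cat(sprintf("  pooled trials: %d\n", x$n_trials_pooled))
  if (isTRUE(x$underpowered)) {
    cat("  NOTE: configuration was underpowered; some results unavailable\n")
  }
  cat(sprintf("  update ~ surprise + confidence:        rho = %.3f\n",
              x$update_rho))
  cat(sprintf("  update ~ surprise * confidence:        rho = %.3f\n",
              x$update_rho_interaction))
  if (!is.null(x$confidence)) {
    cat("  confidence regressions (z-scored outcome), group mean +/- s.e.m.:\n")
    s <- x$confidence$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-26s %7.3f +/- %.3f  (t = %6.2f, d = %5.2f)\n",
                  s$statistic[i], s$mean[i], s$sem[i], s$t[i], s$cohen_d[i]))
    }
  }
  invisible(x)
}

#' Binning experiment: shared measurement noise vs. slow coupling
#'
#' Reproduces, on synthetic signals, the logic that trial binning
#' suppresses a spurious power/ERF coupling caused by shared
#' measurement noise while sparing the true (slow, confidence-driven)
#' coupling. For each bin size, the measured ERF is regressed per
#' subject on surprise, residual confidence and measured power (all
#' binned, in raw generative units so coefficients are comparable
#' across bin sizes), and the group-level t of the power coefficient is
#' reported.
#'
#' The true power coupling is negative (power suppresses the response;
#' see [neuro_sim_params()]) while the shared-noise artifact is
#' positive, so the unbinned regression is biased toward zero or even
#' the wrong sign; as the bin size grows the artifact (white at the
#' trial timescale) averages out and the coefficient converges on the
#' true negative coupling, making its t-value increasingly negative.
#'
#' @param config a [task_config()].
#' @param params a [neuro_sim_params()].
#' @param bin_sizes integer vector of bin sizes (default 1:10).
#' @return data.frame with one row per bin size: `bin_size`,
#'   `power_coef` (group mean), `sem`, `t`, `p`.
#' @export
run_s3_experiment <- function(config, params = neuro_sim_params(),
                              bin_sizes = 1:10) {
  stopifnot(all(bin_sizes >= 1))
  cohort <- simulate_observer_cohort(config)
  seeds <- spawn_seeds(config$seed + 1L, config$n_subjects)
  per_subject <- lapply(seq_len(config$n_subjects), function(s) {
    tr <- cohort$subject_traces[[s]]
    sig <- simulate_power_erf(tr, params, seed = seeds[s])
    d <- as.data.frame(tr)
    ok <- !d$flagged & !is.na(d$confidence) & !is.na(d$surprise)
    sig$resid_conf <- residual_confidence(d$confidence[ok], d$p_next[ok])
    sig$session <- d$session[ok]
    sig
  })
  rows <- lapply(bin_sizes, function(b) {
    coefs <- vapply(per_subject, function(sig) {
      m <- bin_trials(
        sig[, c("erf_meas", "surp", "resid_conf", "power_meas")],
        bin_size = b, session = sig$session
      )
      fit <- mass_univariate_regression(
        Y = m[, "erf_meas", drop = FALSE],
        X = m[, c("surp", "resid_conf", "power_meas")],
        zscore_x = FALSE
      )
      fit$coef["power_meas", 1]
    }, numeric(1))
    # noise-free parameter settings make the fit exact and the
    # between-subject variance zero; report the t as infinite-degenerate
    m <- mean(coefs)
    sem <- stats::sd(coefs) / sqrt(length(coefs))
    tval <- if (sem > 0) m / sem else sign(m) * Inf
    pval <- if (sem > 0) {
      2 * stats::pt(-abs(tval), df = length(coefs) - 1)
    } else {
      NA_real_
    }
    data.frame(bin_size = b, power_coef = m, sem = sem, t = tval, p = pval)
  })
  do.call(rbind, rows)
}

#' Decoding experiment: predict confidence reports from band power
#'
#' Simulates per-question multi-frequency power features with a planted
#' confidence loading in the low-beta band (15-20 Hz), simulates noisy
#' confidence reports, and decodes the reports from the features with
#' interleaved cross-validated ridge regression, per subject. Feature
#' noise is smooth across the frequency axis (AR(1) with coefficient
#' `freq_smoothness`), emulating the strong correlation of band power
#' estimates at neighboring frequencies; with white feature noise the
#' effective dimensionality would be unrealistically high for the small
#' ridge penalty. The decodable signal is weak by construction (reports
#' correlate only `report_rho` with optimal confidence), so per-subject
#' accuracies are small and the group test needs the full cohort.
#'
#' @param config a [task_config()].
#' @param params a [neuro_sim_params()].
#' @param freqs frequencies (Hz) of the feature bins (default 6:40).
#' @param planted_band frequency range carrying the confidence loading
#'   (default `c(15, 20)`).
#' @param planted_gain loading strength (default 0.5; 0 plants nothing).
#' @param freq_smoothness across-frequency AR(1) coefficient of the
#'   feature noise (default 0.9).
#' @param penalty,n_folds passed to [ridge_cv()].
#' @return list with `rho` (per-subject out-of-sample correlation),
#'   `group` ([group_ttest()] on `rho`), `weights` (subjects x
#'   frequencies full-data ridge weights) and `freqs`.
#' @export
run_decoding_experiment <- function(config, params = neuro_sim_params(),
                                    freqs = 6:40,
                                    planted_band = c(15, 20),
                                    planted_gain = 0.5,
                                    freq_smoothness = 0.9,
                                    penalty = 0.01, n_folds = 20) {
  cohort <- simulate_observer_cohort(config)
  seeds <- spawn_seeds(config$seed + 2L, 2L * config$n_subjects)
  in_band <- freqs >= planted_band[1] & freqs <= planted_band[2]
  res <- lapply(seq_len(config$n_subjects), function(s) {
    tr <- cohort$subject_traces[[s]]
    # question trials per session, re-indexed into the stacked trace
    d <- as.data.frame(tr)
    offs <- c(0, cumsum(table(d$session)))
    qs <- unlist(lapply(seq_along(cohort$task[[s]]), function(ss) {
      cohort$task[[s]][[ss]]$questions + offs[ss]
    }))
    rep <- simulate_reports(tr, qs, params, seed = seeds[s])
    set.seed(seeds[config$n_subjects + s])
    n_q <- nrow(rep)
    # noise smooth across the frequency axis, unit marginal SD per bin
    feat <- t(vapply(seq_len(n_q), function(i) {
      ar1_noise(length(freqs), rho = freq_smoothness, sd = 1)
    }, numeric(length(freqs))))
    feat[, in_band] <- feat[, in_band] + planted_gain * rep$conf
    cv <- ridge_cv(feat, rep$report, penalty = penalty, n_folds = n_folds)
    list(rho = cv$rho, weights = cv$weights)
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  weights <- do.call(rbind, lapply(res, `[[`, "weights"))
  colnames(weights) <- as.character(freqs)
  list(rho = rho, group = group_ttest(rho), weights = weights,
       freqs = freqs)
}
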