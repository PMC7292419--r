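#' Parameters of the synthetic neural and pupil generators
#'
#' The generative model couples single-trial signals to the ideal
#' observer's z-scored confidence (CONF) and surprise (SURP):
#'
#' \describe{
#'   \item{band power}{`power_neural = beta1 * CONF + eta`, with `eta`
#'     AR(1) noise of stationary SD `sd_eta` and lag-1 autocorrelation
#'     `rho_eta`.}
#'   \item{evoked response}{`erf_neural = -(beta2 * SURP + beta3 *
#'     power_neural) + eps_erf`, white noise of SD `sd_eps`. Both
#'     couplings weaken the measured deflection: surprise drives the
#'     response and power (a confidence proxy) suppresses it — the
#'     confidence-weighting prediction. The true power coupling is
#'     therefore *opposite in sign* to the shared-noise artifact below,
#'     which is what makes the binning analysis diagnostic.}
#'   \item{measurement}{one shared white-noise realization `eps_common`
#'     (SD `sd_eps`) is added to *both* measured signals:
#'     `power_meas = power_neural + eps_common`,
#'     `erf_meas = erf_neural + eps_common`. The shared term creates a
#'     spurious fast-timescale power/ERF coupling that trial binning is
#'     designed to suppress.}
#'   \item{pupil}{`pupil_tonic = pupil_conf_gain * CONF + AR(1) noise`
#'     (lag-1 autocorrelation `pupil_rho`);
#'     `pupil_phasic = pupil_surprise_gain * SURP + white noise`.}
#'   \item{reports}{confidence reports on question trials are a logistic
#'     squash of a scaled, noisy copy of CONF, with the gain calibrated
#'     so that the report/CONF correlation is about `report_rho`.}
#' }
#'
#' The neural coupling defaults are deliberately round, illustrative
#' values (not fit to data); the pupil gains are plumbing defaults with
#' only their signs constrained (tonic pupil larger under low
#' confidence, phasic dilation larger under surprise).
#'
#' @param beta1 confidence-to-power coupling (default 0.25).
#' @param beta2 surprise-to-ERF coupling (default 0.25).
#' @param beta3 power-to-ERF coupling (default 0.5).
#' @param sd_eta stationary SD of the power noise (default 1).
#' @param rho_eta lag-1 autocorrelation of the power noise (default 0.5).
#' @param sd_eps SD of the ERF noise and of the shared measurement noise
#'   (default 1).
#' @param pupil_conf_gain tonic pupil/confidence coupling (default -0.1,
#'   negative).
#' @param pupil_surprise_gain phasic pupil/surprise coupling (default
#'   0.2, positive).
#' @param pupil_rho lag-1 autocorrelation of the tonic pupil noise
#'   (default 0.75).
#' @param report_rho target correlation between simulated reports and
#'   optimal confidence (default 0.23).
#' @return an object of class `neuro_sim_params`.
#' @export
neuro_sim_params <- function(beta1 = 0.25, beta2 = 0.25, beta3 = 0.5,
                             sd_eta = 1, rho_eta = 0.5, sd_eps = 1,
                             pupil_conf_gain = -0.1,
                             pupil_surprise_gain = 0.2,
                             pupil_rho = 0.75,
                             report_rho = 0.23) {
  stopifnot(sd_eta >= 0, sd_eps >= 0,
            abs(rho_eta) < 1, abs(pupil_rho) < 1,
            report_rho > -1, report_rho <= 1)
  structure(
    list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
         sd_eta = sd_eta, rho_eta = rho_eta, sd_eps = sd_eps,
         pupil_conf_gain = pupil_conf_gain,
         pupil_surprise_gain = pupil_surprise_gain,
         pupil_rho = pupil_rho, report_rho = report_rho),
    class = "neuro_sim_params"
  )
}

#' Stationary AR(1) Gaussian noise
#'
#' @param n length.
#' @param rho lag-1 autocorrelation, `|rho| < 1`.
#' @param sd stationary (marginal) standard deviation.
#' @return numeric vector; `x[1]` is drawn from the stationary
#'   distribution so the whole series is stationary.
#' @export
ar1_noise <- function(n, rho, sd = 1) {
  stopifnot(abs(rho) < 1)
  if (n == 0) return(numeric(0))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- rho * x[t - 1] + e[t - 1]
  }
  x
}

# z-scored confidence and surprise from a trace, NA rows excluded
trace_conf_surp <- function(trace) {
  d <- as.data.frame(trace)
  ok <- !d$flagged & !is.na(d$confidence) & !is.na(d$surprise)
  list(conf = zscore(d$confidence[ok]), surp = zscore(d$surprise[ok]),
       ok = ok, n = sum(ok))
}

#' Simulate single-trial band power and evoked-response amplitudes
#'
#' See [neuro_sim_params()] for the generative equations. Noise terms
#' are drawn per call from `seed`; identical seeds give identical
#' signals.
#'
#' @param trace an `observer_trace` (rows with undefined confidence or
#'   surprise are dropped).
#' @param params a [neuro_sim_params()].
#' @param seed integer seed.
#' @return data.frame with columns `conf`, `surp` (the z-scored
#'   latents), `power_neural`, `erf_neural`, `power_meas`, `erf_meas`.
#' @export
simulate_power_erf <- function(trace, params, seed) {
  cs <- trace_conf_surp(trace)
  set.seed(seed)
  eta <- ar1_noise(cs$n, params$rho_eta, params$sd_eta)
  eps_erf <- stats::rnorm(cs$n, 0, params$sd_eps)
  eps_common <- stats::rnorm(cs$n, 0, params$sd_eps)
  power_neural <- params$beta1 * cs$conf + eta
  erf_neural <- -(params$beta2 * cs$surp + params$beta3 * power_neural) +
    eps_erf
  data.frame(
    conf = cs$conf, surp = cs$surp,
    power_neural = power_neural,
    erf_neural = erf_neural,
    power_meas = power_neural + eps_common,
    erf_meas = erf_neural + eps_common
  )
}

#' Simulate tonic and phasic pupil size
#'
#' Tonic pupil follows confidence with a negative gain plus
#' autocorrelated noise; phasic pupil follows surprise with a positive
#' gain plus white noise; the two noise streams are independent.
#'
#' @inheritParams simulate_power_erf
#' @return data.frame with columns `conf`, `surp`, `pupil_tonic`,
#'   `pupil_phasic`.
#' @export
simulate_pupil <- function(trace, params, seed) {
  cs <- trace_conf_surp(trace)
  set.seed(seed)
  tonic_noise <- ar1_noise(cs$n, params$pupil_rho, 1)
  phasic_noise <- stats::rnorm(cs$n)
  data.frame(
    conf = cs$conf, surp = cs$surp,
    pupil_tonic = params$pupil_conf_gain * cs$conf + tonic_noise,
    pupil_phasic = params$pupil_surprise_gain * cs$surp + phasic_noise
  )
}

#' Simulate noisy confidence reports on question trials
#'
#' Reports are `plogis(a * CONF + e)`, `e ~ N(0, 1)`, with the gain `a`
#' calibrated by root finding on the realized sample so that the Pearson
#' correlation between report and CONF on question trials is
#' `params$report_rho` (up to the calibration tolerance; with
#' `report_rho` approaching 1 the noise is dropped instead).
#'
#' @param trace an `observer_trace`.
#' @param question_trials integer indices of question trials (e.g. a
#'   `question_schedule`).
#' @param params a [neuro_sim_params()].
#' @param seed integer seed.
#' @return data.frame with `trial`, `conf` (z-scored optimal confidence
#'   at the question) and `report` in `[0, 1]`.
#' @export
simulate_reports <- function(trace, question_trials, params, seed) {
  d <- as.data.frame(trace)
  question_trials <- as.integer(question_trials)
  stopifnot(all(question_trials >= 1), all(question_trials <= nrow(d)))
  q <- question_trials[!d$flagged[question_trials] &
                         !is.na(d$confidence[question_trials])]
  conf <- zscore(d$confidence[q])
  set.seed(seed)
  e <- stats::rnorm(length(conf))
  target <- params$report_rho
  if (target >= 0.999) {
    return(data.frame(trial = q, conf = conf,
                      report = stats::plogis(conf)))
  }
  gap <- function(a) stats::cor(stats::plogis(a * conf + e), conf) - target
  # the realized noise can already correlate above target in small
  # samples; the closest attainable gain is then zero
  a <- if (gap(0) >= 0) 0 else
    stats::uniroot(gap, lower = 0, upper = 200, tol = 1e-6)$root
  data.frame(trial = q, conf = conf,
             report = stats::plogis(a * conf + e))
}
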