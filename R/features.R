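#' z-score a vector
#'
#' @param x numeric vector (no NAs).
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant (or degenerate) vector")
  }
  (x - mean(x)) / s
}

#' Residual confidence: remove prediction-related components
#'
#' Regresses confidence on an intercept, the prediction `p`, its square,
#' `log(p)` and `log(1 - p)`, and returns the residuals. This removes
#' every component of confidence that is (non)linearly explainable by
#' the prediction itself, leaving the part tied to the history of
#' observations.
#'
#' @param confidence numeric vector of confidence values.
#' @param p numeric vector of predictions, strictly inside (0, 1).
#' @return residual vector, orthogonal to all five regressors.
#' @export
residual_confidence <- function(confidence, p) {
  stopifnot(length(confidence) == length(p))
  if (any(p <= 0 | p >= 1)) {
    stop("predictions must lie strictly inside (0, 1)")
  }
  X <- cbind(1, p, p^2, log(p), log1p(-p))
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate trace: prediction design is rank deficient")
  }
  fit <- stats::lm.fit(X, confidence)
  fit$residuals
}

#' Lag-1 (adjacent-trial) Pearson correlation
#'
#' Correlates `x[t]` with `x[t + 1]`, forming pairs only within the
#' blocks defined by `session` (no pair straddles a session boundary).
#'
#' @param x numeric vector.
#' @param session optional block labels, same length as `x`; by default
#'   all values form one block.
#' @return Pearson correlation of the adjacent pairs.
#' @export
adjacent_correlation <- function(x, session = NULL) {
  if (is.null(session)) session <- rep(1L, length(x))
  stopifnot(length(session) == length(x))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant input: correlation undefined")
  pairs <- do.call(rbind, lapply(split(x, session), function(u) {
    if (length(u) < 2) return(NULL)
    cbind(u[-length(u)], u[-1])
  }))
  stats::cor(pairs[, 1], pairs[, 2])
}

#' Average consecutive trials into non-overlapping bins
#'
#' Rows are grouped into consecutive blocks of `bin_size` within each
#' session; each output row is the column-wise mean of one block. A
#' trailing block shorter than `bin_size` is dropped so that all bins
#' average the same number of trials.
#'
#' @param signals numeric matrix or data.frame (trials x variables).
#' @param bin_size number of consecutive trials per bin (>= 1).
#' @param session optional block labels; binning never crosses a
#'   session boundary.
#' @return matrix of binned rows (possibly 0 rows).
#' @export
bin_trials <- function(signals, bin_size, session = NULL) {
  signals <- as.matrix(signals)
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  if (is.null(session)) session <- rep(1L, nrow(signals))
  out <- lapply(split(seq_len(nrow(signals)), session), function(idx) {
    n_bins <- length(idx) %/% bin_size
    if (n_bins == 0L) return(NULL)
    used <- idx[seq_len(n_bins * bin_size)]
    grp <- rep(seq_len(n_bins), each = bin_size)
    apply(signals[used, , drop = FALSE], 2,
          function(col) tapply(col, grp, mean))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    stop("bin_size exceeds every session length: no complete bin")
  }
  res <- do.call(rbind, lapply(out, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1) else m
  }))
  colnames(res) <- colnames(signals)
  rownames(res) <- NULL
  res
}

# stack a list of per-subject traces, excluding flagged/NA rows needed
# for the update regression
pool_update_rows <- function(traces) {
  pooled <- do.call(rbind, lapply(traces, function(tr) {
    d <- as.data.frame(tr)
    d[!d$flagged & !is.na(d$confidence_prior) & !is.na(d$kl_update), ,
      drop = FALSE]
  }))
  if (nrow(pooled) < 100) {
    stop("fewer than 100 usable trials: update regression is underpowered")
  }
  pooled
}

#' How well do surprise and confidence explain the belief update?
#'
#' Pools trials across all supplied traces and fits one OLS regression
#' of the KL belief update on z-scored surprise and z-scored prior
#' confidence (optionally plus their product), with an intercept. The
#' returned statistic is the Pearson correlation between fitted and
#' actual updates: a value near 1 means the update is (mostly) an
#' additive function of surprise and confidence.
#'
#' @param traces a list of `observer_trace` objects (or one trace).
#' @param include_interaction add the surprise-by-confidence product?
#' @return list with `rho` (Pearson correlation, fitted vs actual),
#'   `fit` (the `lm` object) and `n` (trials pooled).
#' @export
update_regression_r <- function(traces, include_interaction = FALSE) {
  if (inherits(traces, "data.frame")) traces <- list(traces)
  pooled <- pool_update_rows(traces)
  zs <- zscore(pooled$surprise)
  zc <- zscore(pooled$confidence_prior)
  fit <- if (include_interaction) {
    stats::lm(pooled$kl_update ~ zs + zc + I(zs * zc))
  } else {
    stats::lm(pooled$kl_update ~ zs + zc)
  }
  list(rho = stats::cor(stats::fitted(fit), pooled$kl_update),
       fit = fit, n = nrow(pooled))
}

# lag a vector by one within session blocks
lag_within <- function(x, session) {
  unsplit(lapply(split(x, session), function(u) c(NA, u[-length(u)])), session)
}

#' Per-subject confidence regressions
#'
#' For each subject (an element of `subject_traces`: a data.frame that
#' stacks the subject's session traces and carries a `session` column),
#' computes the standard battery of confidence statistics. Confidence
#' and the probability estimate are the posterior quantities of
#' [run_observer()] (`confidence`, `p_next`): the model's answers to the
#' task's two questions. All predictors are z-scored within subject; by
#' default the confidence outcome is z-scored too
#' (`zscore_outcome = FALSE` reports coefficients in raw log-precision
#' units).
#'
#' Statistics per subject:
#' * `beta_p2` — the quadratic coefficient in the regression of
#'   confidence on the prediction and its centered square (the square of
#'   the z-scored prediction, which isolates the U-shape from the linear
#'   trend; the raw square is nearly collinear with the prediction).
#' * `beta_prev_surprise`, `beta_log_tsc` — coefficients of the surprise
#'   on the preceding observation and of the log number of observations
#'   since the last true change point, in the joint regression of
#'   confidence on prediction, centered squared prediction, preceding
#'   surprise and log observation count.
#' * `beta_prev_surprise_alone`, `beta_log_tsc_alone` — the same two
#'   effects estimated in standalone single-predictor regressions.
#' * `r_conf_p` — Pearson correlation between confidence and the
#'   probability estimate (near zero: the relation is U-shaped, not
#'   linear).
#' * `r_adjacent_residual`, `r_adjacent_raw` — lag-1 correlation of
#'   residual (see [residual_confidence()]) and raw confidence, pairs
#'   formed within session.
#'
#' @param subject_traces list of per-subject stacked trace data.frames
#'   (see [stack_subject_trace()]).
#' @param zscore_outcome z-score the confidence outcome within subject?
#' @param min_trials minimal usable trials per subject.
#' @return list with `per_subject` (one row per subject) and `summary`
#'   (group mean, s.e.m., t, p, Cohen's d per statistic).
#' @export
confidence_regressions <- function(subject_traces, zscore_outcome = TRUE,
                                   min_trials = 10L) {
  rows <- lapply(seq_along(subject_traces), function(s) {
    d <- as.data.frame(subject_traces[[s]])
    stopifnot(!is.null(d$session))
    d$prev_surprise <- lag_within(d$surprise, d$session)
    d <- d[!d$flagged, , drop = FALSE]
    if (nrow(d) < min_trials) {
      stop("subject ", s, ": fewer than ", min_trials, " usable trials")
    }
    conf <- if (zscore_outcome) zscore(d$confidence) else d$confidence
    zp <- zscore(d$p_next)
    zp2 <- zscore(zp^2)

    beta_p2 <- stats::coef(stats::lm(conf ~ zp + zp2))[["zp2"]]

    ok <- !is.na(d$prev_surprise) & !is.na(d$trials_since_cp)
    dj <- d[ok, , drop = FALSE]
    confj <- if (zscore_outcome) zscore(dj$confidence) else dj$confidence
    zpj <- zscore(dj$p_next)
    joint <- stats::lm(confj ~ zpj + I(zscore(zpj^2)) +
                         zscore(dj$prev_surprise) +
                         zscore(log(dj$trials_since_cp)))
    cj <- stats::coef(joint)
    beta_prev_surprise <- cj[[4]]
    beta_log_tsc <- cj[[5]]
    beta_prev_surprise_alone <-
      stats::coef(stats::lm(confj ~ zscore(dj$prev_surprise)))[[2]]
    ok2 <- !is.na(d$trials_since_cp)
    conf2 <- if (zscore_outcome) zscore(d$confidence[ok2]) else d$confidence[ok2]
    beta_log_tsc_alone <-
      stats::coef(stats::lm(conf2 ~ zscore(log(d$trials_since_cp[ok2]))))[[2]]

    rc <- residual_confidence(d$confidence, d$p_next)
    data.frame(
      subject = s,
      beta_p2 = beta_p2,
      beta_prev_surprise = beta_prev_surprise,
      beta_log_tsc = beta_log_tsc,
      beta_prev_surprise_alone = beta_prev_surprise_alone,
      beta_log_tsc_alone = beta_log_tsc_alone,
      r_conf_p = stats::cor(d$confidence, d$p_next),
      r_adjacent_residual = adjacent_correlation(rc, d$session),
      r_adjacent_raw = adjacent_correlation(d$confidence, d$session)
    )
  })
  per_subject <- do.call(rbind, rows)
  stats_cols <- setdiff(names(per_subject), "subject")
  summary <- do.call(rbind, lapply(stats_cols, function(nm) {
    tt <- group_ttest(per_subject[[nm]])
    data.frame(statistic = nm, mean = tt$mean, sem = tt$sem,
               t = tt$t, p = tt$p, cohen_d = tt$d,
               ci_low = tt$ci[1], ci_high = tt$ci[2])
  }))
  rownames(summary) <- NULL
  list(per_subject = per_subject, summary = summary)
}

#' Stack one subject's session traces into a single data.frame
#'
#' @param session_traces list of `observer_trace` objects, one per
#'   session.
#' @return data.frame with a `session` column prepended.
#' @export
stack_subject_trace <- function(session_traces) {
  do.call(rbind, lapply(seq_along(session_traces), function(i) {
    d <- as.data.frame(session_traces[[i]])
    cbind(session = i, d)
  }))
}
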