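#' Flat prior over the transition-probability grid
#'
#' The observer discretizes the pair \eqn{(\theta_{A|A}, \theta_{B|B})}
#' on a `grid_n` x `grid_n` grid of bin midpoints `(i - 0.5) / grid_n`,
#' which keeps every grid value strictly inside (0, 1) so that no
#' observation ever has zero likelihood and surprise stays finite.
#'
#' @param grid_n grid points per dimension (>= 2).
#' @return an object of class `posterior_grid`: a list with
#'   `grid_values` (the per-dimension support) and `joint` (the
#'   normalized `grid_n` x `grid_n` weight matrix; rows index
#'   \eqn{\theta_{A|A}}, columns \eqn{\theta_{B|B}}).
#' @export
make_prior <- function(grid_n) {
  stopifnot(grid_n >= 2)
  grid_n <- as.integer(grid_n)
  structure(
    list(
      grid_values = (seq_len(grid_n) - 0.5) / grid_n,
      joint = matrix(1 / (grid_n * grid_n), grid_n, grid_n)
    ),
    class = "posterior_grid"
  )
}

new_posterior_grid <- function(grid_values, joint) {
  structure(list(grid_values = grid_values, joint = joint),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  n <- length(x$grid_values)
  cat(sprintf("posterior_grid: %d x %d grid on (%.3g, %.3g)\n",
              n, n, x$grid_values[1], x$grid_values[n]))
  m <- marginal_moments(x, prev_tone = 0L)
  cat(sprintf("  marginal of p(A|A): mean %.4f, var %.5f\n", m[1], m[2]))
  m <- marginal_moments(x, prev_tone = 1L)
  cat(sprintf("  marginal of p(B|B): mean %.4f, var %.5f\n", m[1], m[2]))
  invisible(x)
}

# mean and variance of the relevant marginal: theta_{A|A} (rows) when the
# previous tone is A (0), theta_{B|B} (cols) when it is B (1)
marginal_moments <- function(post, prev_tone) {
  g <- post$grid_values
  m <- if (prev_tone == 0L) rowSums(post$joint) else colSums(post$joint)
  mu <- sum(g * m)
  c(mean = mu, var = sum(g * g * m) - mu * mu)
}

# likelihood of observing `new_tone` after `prev_tone` for every grid cell
likelihood_matrix <- function(grid_values, prev_tone, new_tone) {
  n <- length(grid_values)
  if (prev_tone == 0L) {
    v <- if (new_tone == 0L) grid_values else 1 - grid_values
    matrix(v, n, n)
  } else {
    v <- if (new_tone == 1L) grid_values else 1 - grid_values
    matrix(v, n, n, byrow = TRUE)
  }
}

# change-point transition kernel: with probability p_change both
# probabilities are redrawn from the flat prior over the full grid
apply_transition <- function(post, p_change) {
  n <- length(post$grid_values)
  new_posterior_grid(
    post$grid_values,
    (1 - p_change) * post$joint + p_change / (n * n)
  )
}

#' One forward step of the change-point HMM
#'
#' Applies the change-point transition kernel (mass `1 - p_change` stays
#' put, mass `p_change` is reallocated uniformly over the grid), then
#' multiplies by the likelihood of the new tone given the previous tone,
#' and renormalizes.
#'
#' @param post a normalized `posterior_grid`.
#' @param prev_tone,new_tone tones coded 0 (A) / 1 (B).
#' @param p_change per-trial change-point probability in `[0, 1]`.
#' @return the updated, normalized `posterior_grid`.
#' @export
hmm_step <- function(post, prev_tone, new_tone, p_change) {
  stopifnot(p_change >= 0, p_change <= 1)
  prior <- apply_transition(post, p_change)
  joint <- prior$joint * likelihood_matrix(prior$grid_values, prev_tone, new_tone)
  z <- sum(joint)
  if (z <= 0 || !is.finite(z)) {
    stop("posterior underflow: all grid cells received zero weight")
  }
  new_posterior_grid(prior$grid_values, joint / z)
}

#' Predicted probability of the next tone being A
#'
#' The prediction is the posterior mean of the relevant transition
#' probability, mapped to the probability that the next tone is A:
#' \eqn{E[\theta_{A|A}]} after an A, \eqn{1 - E[\theta_{B|B}]} after a B.
#'
#' @param post a normalized `posterior_grid`.
#' @param prev_tone the conditioning tone, 0 (A) or 1 (B).
#' @return probability in (0, 1).
#' @export
predict_next <- function(post, prev_tone) {
  mu <- marginal_moments(post, prev_tone)[["mean"]]
  if (prev_tone == 0L) mu else 1 - mu
}

#' Shannon surprise of an observation, in bits
#'
#' @param prediction the probability the observer assigned to tone A,
#'   strictly inside (0, 1).
#' @param observed the observed tone, 0 (A) or 1 (B).
#' @return surprise \eqn{-\log_2 p(\mathrm{observed})}, in bits.
#' @export
surprise_bits <- function(prediction, observed) {
  if (any(prediction <= 0 | prediction >= 1)) {
    stop("prediction must lie strictly inside (0, 1)")
  }
  p_obs <- ifelse(observed == 0L, prediction, 1 - prediction)
  -log2(p_obs)
}

#' Confidence as posterior log-precision
#'
#' Confidence about the prediction is the negative natural log of the
#' variance of the relevant marginal (the \eqn{\theta_{A|A}} marginal
#' after an A, the \eqn{\theta_{B|B}} marginal after a B).
#'
#' @param post a normalized `posterior_grid`.
#' @param prev_tone the conditioning tone, 0 (A) or 1 (B).
#' @return `-log(var)` in natural-log units.
#' @export
confidence_logprec <- function(post, prev_tone) {
  v <- marginal_moments(post, prev_tone)[["var"]]
  if (v <= 0) {
    stop("degenerate posterior: zero variance on the relevant marginal")
  }
  -log(v)
}

#' Kullback-Leibler divergence between two grid distributions
#'
#' Computes \eqn{D(q \| p) = \sum_i q_i \log(q_i / p_i)} in nats over the
#' joint grid. Cells with `q = 0` contribute zero; a cell with `q > 0`
#' but `p = 0` is a support mismatch and raises an error.
#'
#' @param q,p normalized `posterior_grid` objects on the same grid.
#' @return divergence in nats (non-negative).
#' @export
kl_divergence <- function(q, p) {
  if (!isTRUE(all.equal(q$grid_values, p$grid_values))) {
    stop("grids differ: KL divergence undefined")
  }
  qi <- q$joint
  pi_ <- p$joint
  if (any(qi > 0 & pi_ <= 0)) {
    stop("support mismatch: q places mass where p has none")
  }
  pos <- qi > 0
  sum(qi[pos] * log(qi[pos] / pi_[pos]))
}

#' Run the Bayes-optimal ideal observer over a tone sequence
#'
#' Iterates the HMM forward recursion with a flat prior and records the
#' per-trial latent variables. Two conventions are recorded side by side:
#'
#' * *prior* quantities at trial t condition on tones 1..t-1 (after the
#'   change-point transition kernel, before seeing tone t): `prediction`
#'   (probability that tone t is A), `surprise` (bits, of tone t given
#'   that prediction) and `confidence_prior`.
#' * *posterior* quantities at trial t condition on tones 1..t: `p_next`
#'   (probability that tone t+1 is A, conditioned on tone t),
#'   `confidence` (log-precision of the relevant marginal given tone t),
#'   and the relevant marginal moments. These are the model's answers to
#'   the task's probability and confidence questions.
#'
#' `kl_update` at trial t is the divergence between the pre-observation
#' belief and the posterior after tone t. Its reference distribution and
#' direction are controlled by `kl_reference` ("transition": the belief
#' after the change-point kernel, the default; "previous": the raw
#' posterior from trial t-1) and `kl_direction` ("prior_to_posterior":
#' \eqn{D(\mathrm{prior} \| \mathrm{posterior})}, the default;
#' "posterior_to_prior": the reverse).
#'
#' Trial 1 has no conditioning tone: its prediction is fixed at 0.5,
#' surprise is 1 bit, `confidence_prior` is `NA` and the trial is
#' flagged (`flagged = TRUE`) for exclusion from regressions.
#'
#' @param seq a `tone_sequence` (or a bare integer vector of tones coded
#'   0/1, in which case `config` must be given).
#' @param config a [task_config()]; defaults to the one attached to
#'   `seq`.
#' @param kl_reference,kl_direction see Details.
#' @param keep_posterior if `TRUE`, the final `posterior_grid` is
#'   attached as attribute `"posterior"`.
#' @return an `observer_trace`: a data.frame with one row per trial and
#'   columns `trial`, `tone`, `prediction`, `surprise`,
#'   `confidence_prior`, `p_next`, `confidence`, `kl_update`,
#'   `posterior_mean_rel`, `posterior_var_rel`, `trials_since_cp`
#'   (NA when the sequence carries no change-point annotation) and
#'   `flagged`.
#' @export
run_observer <- function(seq, config = NULL,
                         kl_reference = c("transition", "previous"),
                         kl_direction = c("prior_to_posterior",
                                          "posterior_to_prior"),
                         keep_posterior = FALSE) {
  kl_reference <- match.arg(kl_reference)
  kl_direction <- match.arg(kl_direction)
  if (inherits(seq, "tone_sequence")) {
    tones <- seq$tones
    tsc <- seq$trials_since_cp
    if (is.null(config)) config <- seq$config
  } else {
    tones <- as.integer(seq)
    tsc <- rep(NA_integer_, length(tones))
  }
  if (is.null(config)) {
    stop("a task_config is required (give `config` or a tone_sequence ",
         "that carries one)")
  }
  n <- length(tones)
  p_c <- config$p_change
  post <- make_prior(config$grid_n)
  g <- post$grid_values
  gn <- length(g)
  flat <- 1 / (gn * gn)

  cols <- c("prediction", "surprise", "confidence_prior", "p_next",
            "confidence", "kl_update", "posterior_mean_rel",
            "posterior_var_rel")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))

  if (n >= 1L) {
    # trial 1: the first tone is equiprobable and carries no information
    # about transition probabilities, so the posterior stays flat
    out[1, "prediction"] <- 0.5
    out[1, "surprise"] <- 1
    out[1, "kl_update"] <- 0
    mv <- marginal_moments(post, tones[1])
    out[1, "p_next"] <- predict_next(post, tones[1])
    out[1, "confidence"] <- -log(mv[["var"]])
    out[1, "posterior_mean_rel"] <- mv[["mean"]]
    out[1, "posterior_var_rel"] <- mv[["var"]]
  }

  joint <- post$joint
  for (t in seq_len(n)[-1]) {
    prev <- tones[t - 1L]
    obs <- tones[t]
    prior <- (1 - p_c) * joint + p_c * flat
    prior_for_kl <- if (kl_reference == "transition") prior else joint

    marg <- if (prev == 0L) rowSums(prior) else colSums(prior)
    mu <- sum(g * marg)
    v <- sum(g * g * marg) - mu * mu
    p_a <- if (prev == 0L) mu else 1 - mu
    out[t, "prediction"] <- p_a
    out[t, "surprise"] <- -log2(if (obs == 0L) p_a else 1 - p_a)
    out[t, "confidence_prior"] <- -log(v)

    lik <- if (prev == 0L) {
      if (obs == 0L) g else 1 - g
    } else {
      if (obs == 1L) g else 1 - g
    }
    joint <- if (prev == 0L) prior * lik else sweep(prior, 2, lik, `*`)
    z <- sum(joint)
    if (z <= 0 || !is.finite(z)) {
      stop("posterior underflow at trial ", t)
    }
    joint <- joint / z

    if (kl_direction == "prior_to_posterior") {
      pos <- prior_for_kl > 0
      out[t, "kl_update"] <-
        sum(prior_for_kl[pos] * log(prior_for_kl[pos] / joint[pos]))
    } else {
      pos <- joint > 0
      out[t, "kl_update"] <-
        sum(joint[pos] * log(joint[pos] / prior_for_kl[pos]))
    }

    marg2 <- if (obs == 0L) rowSums(joint) else colSums(joint)
    mu2 <- sum(g * marg2)
    v2 <- sum(g * g * marg2) - mu2 * mu2
    out[t, "p_next"] <- if (obs == 0L) mu2 else 1 - mu2
    out[t, "confidence"] <- -log(v2)
    out[t, "posterior_mean_rel"] <- mu2
    out[t, "posterior_var_rel"] <- v2
  }

  trace <- data.frame(
    trial = seq_len(n),
    tone = tones,
    out,
    trials_since_cp = tsc,
    flagged = c(TRUE, rep(FALSE, max(0L, n - 1L)))[seq_len(n)]
  )
  class(trace) <- c("observer_trace", "data.frame")
  if (keep_posterior) {
    attr(trace, "posterior") <- new_posterior_grid(g, joint)
  }
  trace
}

#' Serialize an observer trace to CSV
#'
#' @param trace an `observer_trace`.
#' @param file path to write.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(file)
}

#' Read an observer trace written by [write_trace_csv()]
#'
#' @param file path to a trace CSV.
#' @return an `observer_trace`.
#' @export
read_trace_csv <- function(file) {
  trace <- utils::read.csv(file)
  class(trace) <- c("observer_trace", "data.frame")
  trace
}
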