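#' Task configuration
#'
#' Bundles every constant of the generative process and of the ideal
#' observer's numerical inference into a single validated object.
#'
#' The task presents a sequence of two tones, A and B (coded 0 and 1).
#' Tones are drawn from first-order transition probabilities
#' \eqn{\theta = (p(A|A), p(B|B))} that are piecewise constant: on every
#' trial there is a fixed probability `p_change` that both transition
#' probabilities are resampled ("change point"). Resampling is uniform on
#' `[resample_low, resample_high]`, subject to the constraint that the
#' odds of at least one of the two probabilities change by a factor of at
#' least `min_fold_change`.
#'
#' @param p_change per-trial change-point probability (default 1/75).
#' @param n_trials number of tones per session (default 380).
#' @param n_sessions sessions per subject (default 4).
#' @param n_subjects number of simulated subjects (default 24).
#' @param resample_low,resample_high bounds of the uniform resampling
#'   interval for transition probabilities (defaults 0.1 and 0.9).
#' @param min_fold_change minimal odds-ratio change required for at least
#'   one transition probability at a change point (default 4).
#' @param grid_n number of grid points per dimension used by the ideal
#'   observer for numerical integration (default 20).
#' @param question_gap_median,question_gap_sd median and standard
#'   deviation of the inter-question interval, in trials (defaults 13
#'   and 4.4).
#' @param seed master seed from which all per-subject/per-session seeds
#'   are spawned.
#' @return an object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config(n_subjects = 2, n_sessions = 1)
#' @export
task_config <- function(p_change = 1 / 75,
                        n_trials = 380L,
                        n_sessions = 4L,
                        n_subjects = 24L,
                        resample_low = 0.1,
                        resample_high = 0.9,
                        min_fold_change = 4,
                        grid_n = 20L,
                        question_gap_median = 13,
                        question_gap_sd = 4.4,
                        seed = 1L) {
  stopifnot(
    p_change >= 0, p_change < 1,
    resample_low < resample_high,
    resample_low > 0, resample_high < 1,
    min_fold_change >= 1,
    grid_n >= 2,
    n_trials >= 0, n_sessions >= 1, n_subjects >= 1
  )
  structure(
    list(
      p_change = p_change,
      n_trials = as.integer(n_trials),
      n_sessions = as.integer(n_sessions),
      n_subjects = as.integer(n_subjects),
      resample_low = resample_low,
      resample_high = resample_high,
      min_fold_change = min_fold_change,
      grid_n = as.integer(grid_n),
      question_gap_median = question_gap_median,
      question_gap_sd = question_gap_sd,
      seed = as.integer(seed)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration\n")
  cat(sprintf("  %d subjects x %d sessions x %d trials\n",
              x$n_subjects, x$n_sessions, x$n_trials))
  cat(sprintf("  p(change point) = %.4g, resampling U[%.2g, %.2g], >= %.3g-fold odds change\n",
              x$p_change, x$resample_low, x$resample_high, x$min_fold_change))
  cat(sprintf("  observer grid: %d x %d, master seed %d\n",
              x$grid_n, x$grid_n, x$seed))
  invisible(x)
}

# draw a transition-probability pair, rejecting candidates whose odds do
# not change enough relative to `old` (NULL for the initial draw)
draw_theta <- function(config, old = NULL, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    theta <- stats::runif(2, config$resample_low, config$resample_high)
    if (is.null(old)) {
      return(theta)
    }
    delta <- abs(log(theta / (1 - theta)) - log(old / (1 - old)))
    if (max(delta) >= log(config$min_fold_change)) {
      return(theta)
    }
  }
  stop("rejection sampling failed: the fold-change constraint is infeasible ",
       "for this configuration")
}

#' Generate one tone sequence from the change-point generative process
#'
#' Draws a binary tone sequence of length `config$n_trials`. The first
#' tone is equiprobable; every later tone is drawn from the transition
#' probability active on that trial, conditioned on the previous tone.
#' Change points occur independently on each trial (from trial 2 on) with
#' probability `config$p_change`, at which point both transition
#' probabilities are resampled under the fold-change constraint.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same seed reproduces the sequence
#'   exactly.
#' @return an object of class `tone_sequence`: a list with elements
#'   `tones` (integer, 0 = A, 1 = B), `theta_true` (n x 2 matrix of
#'   per-trial \eqn{(p(A|A), p(B|B))}), `changepoints` (trial indices at
#'   which theta changed), `trials_since_cp` (1-based observation count
#'   within the current stable segment) and `config`.
#' @export
generate_sequence <- function(config, seed) {
  set.seed(seed)
  n <- config$n_trials
  tones <- integer(n)
  theta_true <- matrix(NA_real_, n, 2,
                       dimnames = list(NULL, c("p_AA", "p_BB")))
  changepoints <- integer(0)
  trials_since_cp <- integer(n)
  if (n == 0L) {
    return(structure(
      list(tones = tones, theta_true = theta_true,
           changepoints = changepoints, trials_since_cp = trials_since_cp,
           config = config),
      class = "tone_sequence"
    ))
  }
  theta <- draw_theta(config)
  count <- 0L
  for (t in seq_len(n)) {
    if (t > 1L && stats::runif(1) < config$p_change) {
      theta <- draw_theta(config, old = theta)
      changepoints <- c(changepoints, t)
      count <- 0L
    }
    count <- count + 1L
    trials_since_cp[t] <- count
    theta_true[t, ] <- theta
    if (t == 1L) {
      tones[t] <- stats::rbinom(1, 1, 0.5)
    } else {
      p_a <- if (tones[t - 1L] == 0L) theta[1] else 1 - theta[2]
      tones[t] <- stats::rbinom(1, 1, 1 - p_a)
    }
  }
  structure(
    list(tones = tones, theta_true = theta_true,
         changepoints = changepoints, trials_since_cp = trials_since_cp,
         config = config),
    class = "tone_sequence"
  )
}

#' Generate a question-trial schedule
#'
#' Questions occasionally interrupt the tone sequence. Inter-question
#' gaps are drawn as `round(Normal(median, sd))`, truncated below at 2
#' trials, until the end of the session is reached.
#'
#' @param config a [task_config()]; uses `n_trials`,
#'   `question_gap_median` and `question_gap_sd`.
#' @param seed integer seed.
#' @return integer vector of sorted question trial indices (possibly
#'   empty), of class `question_schedule`.
#' @export
generate_question_schedule <- function(config, seed) {
  set.seed(seed)
  gaps <- integer(0)
  pos <- 0
  repeat {
    g <- max(2L, as.integer(round(stats::rnorm(1, config$question_gap_median,
                                               config$question_gap_sd))))
    if (pos + g > config$n_trials) break
    pos <- pos + g
    gaps <- c(gaps, pos)
  }
  structure(as.integer(gaps), class = "question_schedule")
}

#' Spawn reproducible child seeds from a master seed
#'
#' A single master seed deterministically yields one child seed per
#' (subject, session) cell plus auxiliary streams, so that multi-subject
#' batches are reproducible and each cell is an independent stream.
#'
#' @param master_seed integer.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the complete multi-subject task
#'
#' Generates `n_subjects x n_sessions` tone sequences and question
#' schedules, with per-cell seeds spawned from `config$seed`.
#'
#' @param config a [task_config()].
#' @return a list with one element per subject; each subject is a list of
#'   sessions, each holding `sequence` (a `tone_sequence`) and
#'   `questions` (a `question_schedule`).
#' @export
simulate_task <- function(config) {
  n_cells <- config$n_subjects * config$n_sessions
  seeds <- spawn_seeds(config$seed, 2L * n_cells)
  seq_seeds <- matrix(seeds[seq_len(n_cells)],
                      config$n_subjects, config$n_sessions)
  q_seeds <- matrix(seeds[n_cells + seq_len(n_cells)],
                    config$n_subjects, config$n_sessions)
  lapply(seq_len(config$n_subjects), function(s) {
    lapply(seq_len(config$n_sessions), function(ss) {
      list(
        sequence = generate_sequence(config, seed = seq_seeds[s, ss]),
        questions = generate_question_schedule(config, seed = q_seeds[s, ss])
      )
    })
  })
}

#' Serialize a tone sequence to CSV
#'
#' Columns: trial, tone, p_AA_true, p_BB_true, is_changepoint,
#' trials_since_cp.
#'
#' @param x a `tone_sequence`.
#' @param file path to write.
#' @export
write_sequence_csv <- function(x, file) {
  df <- data.frame(
    trial = seq_along(x$tones),
    tone = x$tones,
    p_AA_true = x$theta_true[, 1],
    p_BB_true = x$theta_true[, 2],
    is_changepoint = as.integer(seq_along(x$tones) %in% x$changepoints),
    trials_since_cp = x$trials_since_cp
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a tone sequence written by [write_sequence_csv()]
#'
#' @param file path to a sequence CSV.
#' @param config optional [task_config()] to attach.
#' @return a `tone_sequence`.
#' @export
read_sequence_csv <- function(file, config = NULL) {
  df <- utils::read.csv(file)
  structure(
    list(
      tones = as.integer(df$tone),
      theta_true = cbind(p_AA = df$p_AA_true, p_BB = df$p_BB_true),
      changepoints = df$trial[df$is_changepoint == 1L],
      trials_since_cp = as.integer(df$trials_since_cp),
      config = config
    ),
    class = "tone_sequence"
  )
}
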