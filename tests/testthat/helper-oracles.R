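# Independent oracles used to validate the HMM forward recursion and the
# grid moments. These deliberately share no code with the package
# internals: the enumeration oracle sums over every change-point
# configuration explicitly, and the moment oracle is direct quadrature.

# Exact posterior over the joint transition-probability grid after a
# short sequence, by brute-force enumeration of all 2^(n-1) change-point
# configurations. A configuration is the set of trials (among 2..n)
# before whose observation both probabilities were redrawn from the flat
# grid prior. The first tone is equiprobable and carries no information.
oracle_enum_posterior <- function(tones, p_change, grid_n) {
  g <- (seq_len(grid_n) - 0.5) / grid_n
  n <- length(tones)
  flat_cell <- 1 / (grid_n * grid_n)
  # per-trial likelihood over the joint grid (rows: p_AA, cols: p_BB)
  lik_t <- function(t) {
    prev <- tones[t - 1]; obs <- tones[t]
    if (prev == 0) {
      v <- if (obs == 0) g else 1 - g
      matrix(v, grid_n, grid_n)
    } else {
      v <- if (obs == 1) g else 1 - g
      matrix(v, grid_n, grid_n, byrow = TRUE)
    }
  }
  accum <- matrix(0, grid_n, grid_n)
  n_cp_slots <- n - 1
  for (code in 0:(2^n_cp_slots - 1)) {
    cps <- which(bitwAnd(code, 2^(seq_len(n_cp_slots) - 1)) > 0) + 1L
    prior_c <- p_change^length(cps) * (1 - p_change)^(n_cp_slots - length(cps))
    if (prior_c == 0) next
    starts <- c(1L, cps)
    ends <- c(cps - 1L, n)
    seg_lik <- function(a, b) {
      L <- matrix(flat_cell, grid_n, grid_n)
      lo <- max(a, 2L)
      if (lo <= b) for (t in lo:b) L <- L * lik_t(t)
      L
    }
    w <- prior_c
    k <- length(starts)
    for (i in seq_len(k - 1)) {
      if (starts[i] > ends[i]) next
      w <- w * sum(seg_lik(starts[i], ends[i]))
    }
    last <- if (starts[k] > ends[k]) {
      matrix(flat_cell, grid_n, grid_n)
    } else {
      seg_lik(starts[k], ends[k])
    }
    accum <- accum + w * last
  }
  accum / sum(accum)
}

# mean/variance of a Beta(a, b)-shaped density evaluated on the midpoint
# grid (direct quadrature; the conjugate-counting oracle)
grid_beta_moments <- function(grid_n, a, b) {
  g <- (seq_len(grid_n) - 0.5) / grid_n
  w <- g^(a - 1) * (1 - g)^(b - 1)
  w <- w / sum(w)
  mu <- sum(g * w)
  c(mean = mu, var = sum(g^2 * w) - mu^2)
}

# posterior_grid with all mass placed on the given (row, col) cells
point_mass_grid <- function(grid_n, cells, mass = NULL) {
  post <- make_prior(grid_n)
  joint <- matrix(0, grid_n, grid_n)
  if (is.null(mass)) mass <- rep(1 / nrow(cells), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    joint[cells[i, 1], cells[i, 2]] <- mass[i]
  }
  post$joint <- joint
  post
}

# small mock observer trace with the columns the simulators need
mock_trace <- function(confidence, surprise, p_next = NULL) {
  n <- length(confidence)
  data.frame(
    trial = seq_len(n),
    tone = rep_len(c(0L, 1L), n),
    prediction = rep(0.5, n),
    surprise = surprise,
    confidence_prior = confidence,
    p_next = if (is.null(p_next)) rep(0.5, n) else p_next,
    confidence = confidence,
    kl_update = rep(0.1, n),
    posterior_mean_rel = rep(0.5, n),
    posterior_var_rel = rep(0.05, n),
    trials_since_cp = seq_len(n),
    flagged = rep(FALSE, n)
  )
}
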