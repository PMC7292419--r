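test_that("the flat prior is uniform, normalized and symmetric", {
  p20 <- make_prior(20)
  expect_equal(dim(p20$joint), c(20, 20))
  expect_true(all(p20$joint == 1 / 400))
  expect_equal(sum(p20$joint), 1)
  p2 <- make_prior(2)
  expect_true(all(p2$joint == 0.25))
  expect_equal(predict_next(p20, 0L), 0.5)
  expect_equal(predict_next(p20, 1L), 0.5)
  expect_true(all(p20$grid_values > 0 & p20$grid_values < 1))
  expect_error(make_prior(1))
})

test_that("predictions map the relevant marginal mean onto P(next = A)", {
  # grid_n = 5 midpoints are 0.1 0.3 0.5 0.7 0.9: put all mass on
  # (p_AA = 0.9, p_BB = 0.7)
  post <- point_mass_grid(5, cells = rbind(c(5, 4)))
  expect_equal(predict_next(post, 0L), 0.9)
  expect_equal(predict_next(post, 1L), 1 - 0.7)
})

test_that("surprise follows the closed forms and rejects certainty", {
  expect_equal(surprise_bits(0.5, 0L), 1)
  expect_equal(surprise_bits(0.5, 1L), 1)
  expect_equal(surprise_bits(0.25, 0L), 2)
  expect_equal(surprise_bits(0.25, 1L), -log2(0.75))
  expect_error(surprise_bits(0, 0L))
  expect_error(surprise_bits(1, 1L))
})

test_that("confidence equals the quadrature log-precision of the marginal", {
  # flat marginal on the 20-point midpoint grid: quadrature variance
  g <- (1:20 - 0.5) / 20
  v_flat <- mean(g^2) - mean(g)^2
  expect_equal(v_flat, (1 - 1 / 400) / 12) # midpoint-grid uniform variance
  expect_equal(confidence_logprec(make_prior(20), 0L), -log(v_flat))
  expect_equal(confidence_logprec(make_prior(20), 0L), 2.4875, tolerance = 1e-4)

  # two-point marginal at grid values 0.275 and 0.725 (cells 6 and 15),
  # equal mass: variance = 0.225^2 = 0.050625 by hand
  post <- point_mass_grid(20, cells = rbind(c(6, 1), c(15, 1)))
  expect_equal(confidence_logprec(post, 0L), -log(0.050625))
  expect_equal(confidence_logprec(post, 0L), 2.983, tolerance = 1e-3)

  # confidence increases monotonically as the posterior sharpens
  sharper <- point_mass_grid(20, cells = rbind(c(9, 1), c(12, 1)))
  expect_gt(confidence_logprec(sharper, 0L), confidence_logprec(post, 0L))
  degenerate <- point_mass_grid(20, cells = rbind(c(9, 1)))
  expect_error(confidence_logprec(degenerate, 0L), "degenerate")
})

test_that("KL divergence obeys its closed forms and the Gibbs inequality", {
  flat <- make_prior(10)
  expect_equal(kl_divergence(flat, flat), 0)
  # all q-mass on one cell of p-mass 1/100
  q <- point_mass_grid(10, cells = rbind(c(3, 7)))
  expect_equal(kl_divergence(q, flat), log(100))
  set.seed(1)
  for (i in 1:20) {
    a <- make_prior(8); a$joint <- matrix(rexp(64), 8, 8); a$joint <- a$joint / sum(a$joint)
    b <- make_prior(8); b$joint <- matrix(rexp(64), 8, 8); b$joint <- b$joint / sum(b$joint)
    expect_gte(kl_divergence(a, b), 0)
  }
  zeroed <- make_prior(10)
  zeroed$joint[3, 7] <- 0
  zeroed$joint <- zeroed$joint / sum(zeroed$joint)
  expect_error(kl_divergence(q, zeroed), "support mismatch")
})

test_that("a certain change point resets the posterior to the prior", {
  sharp <- point_mass_grid(10, cells = rbind(c(2, 9)))
  stepped <- hmm_step(sharp, prev_tone = 0L, new_tone = 0L, p_change = 1)
  # transition with p_change = 1 wipes the input; result is flat x likelihood
  flat_stepped <- hmm_step(make_prior(10), 0L, 0L, p_change = 1)
  expect_equal(stepped$joint, flat_stepped$joint)
  expect_equal(sum(stepped$joint), 1, tolerance = 1e-12)
})

test_that("hmm_step output stays normalized over random updates", {
  set.seed(4)
  post <- make_prior(20)
  for (i in 1:200) {
    post <- hmm_step(post, sample(0:1, 1), sample(0:1, 1), p_change = 1 / 75)
    expect_equal(sum(post$joint), 1, tolerance = 1e-12)
    expect_true(all(post$joint >= 0))
  }
})

test_that("with no volatility the observer reduces to conjugate counting", {
  # k repeats of A after A: relevant marginal is the gridded Beta(k+1, 1)
  cfg <- task_config(p_change = 0, grid_n = 201, n_trials = 11)
  trace <- run_observer(rep(0L, 11), cfg)
  k <- 10 # A-after-A observations
  oracle <- grid_beta_moments(201, a = k + 1, b = 1)
  expect_equal(trace$posterior_mean_rel[11], oracle[["mean"]], tolerance = 1e-12)
  expect_equal(trace$posterior_var_rel[11], oracle[["var"]], tolerance = 1e-12)
  # and the grid mean approximates the continuous Beta mean (k+1)/(k+2)
  expect_equal(trace$posterior_mean_rel[11], (k + 1) / (k + 2), tolerance = 1e-3)
})

test_that("the forward recursion equals brute-force change-point enumeration", {
  set.seed(11)
  cases <- list(
    list(n = 8, grid_n = 5, p_change = 0.1),
    list(n = 10, grid_n = 7, p_change = 1 / 75),
    list(n = 12, grid_n = 11, p_change = 0.3),
    list(n = 6, grid_n = 9, p_change = 0.9)
  )
  for (cs in cases) {
    tones <- sample(0:1, cs$n, replace = TRUE)
    cfg <- task_config(p_change = cs$p_change, grid_n = cs$grid_n,
                       n_trials = cs$n)
    trace <- run_observer(tones, cfg, keep_posterior = TRUE)
    hmm_post <- attr(trace, "posterior")$joint
    oracle <- oracle_enum_posterior(tones, cs$p_change, cs$grid_n)
    expect_lt(max(abs(hmm_post - oracle)), 1e-10)
  }
})

test_that("trial one is flagged and maximally uncertain", {
  cfg <- task_config(n_trials = 1)
  trace <- run_observer(0L, cfg)
  expect_equal(nrow(trace), 1)
  expect_true(trace$flagged[1])
  expect_equal(trace$prediction[1], 0.5)
  expect_equal(trace$surprise[1], 1)
  expect_true(is.na(trace$confidence_prior[1]))
})

test_that("confidence grows linearly in the log observation count in stable stretches", {
  cfg <- task_config(p_change = 1 / 75, n_trials = 300)
  trace <- run_observer(rep(0L, 300), cfg)
  # within one mean segment length (75 trials) the growth is close to
  # linear in log n; beyond that the change-point hazard caps precision
  w <- 2:75
  fit <- lm(trace$confidence[w] ~ log(trace$trial[w]))
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
  # hazard-induced saturation: the late trace falls below the
  # extrapolated unbounded log growth
  extrapolated <- coef(fit)[1] + coef(fit)[2] * log(300)
  expect_lt(trace$confidence[300], extrapolated)
})

test_that("surprise spikes and confidence drops after a hard change point", {
  cfg <- task_config(n_trials = 80)
  tones <- c(rep(0L, 40), rep(1L, 40)) # A-heavy regime then B-heavy regime
  trace <- run_observer(tones, cfg)
  expect_gt(trace$surprise[41], max(trace$surprise[30:40]))
  expect_lt(min(trace$confidence_prior[42:51]), trace$confidence_prior[41])
})

test_that("KL conventions differ but are all non-negative", {
  cfg <- task_config(n_trials = 60)
  sq <- generate_sequence(cfg, seed = 2)
  tr_default <- run_observer(sq, cfg)
  tr_prev <- run_observer(sq, cfg, kl_reference = "previous")
  tr_rev <- run_observer(sq, cfg, kl_direction = "posterior_to_prior")
  for (tr in list(tr_default, tr_prev, tr_rev)) {
    expect_true(all(tr$kl_update >= 0))
    expect_true(all(is.finite(tr$kl_update)))
  }
  expect_false(isTRUE(all.equal(tr_default$kl_update, tr_prev$kl_update)))
  expect_false(isTRUE(all.equal(tr_default$kl_update, tr_rev$kl_update)))
})

test_that("observer traces round-trip through CSV", {
  cfg <- task_config(n_trials = 40)
  sq <- generate_sequence(cfg, seed = 8)
  trace <- run_observer(sq, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, f)
  back <- read_trace_csv(f)
  expect_equal(back$confidence, trace$confidence)
  expect_equal(back$kl_update, trace$kl_update)
  expect_s3_class(back, "observer_trace")
})
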