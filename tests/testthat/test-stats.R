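test_that("mass-univariate regression recovers exact coefficients", {
  set.seed(1)
  n <- 200
  x <- zscore(rnorm(n))
  Y <- matrix(2 * x, n, 5) # same noiseless signal at 5 timepoints
  fit <- mass_univariate_regression(Y, cbind(x = x))
  expect_equal(unname(fit$coef["x", ]), rep(2, 5), tolerance = 1e-10)
  expect_equal(unname(fit$coef["intercept", ]), rep(0, 5), tolerance = 1e-10)
})

test_that("t-values under the null are standard normal", {
  set.seed(2)
  n <- 2000
  Y <- matrix(rnorm(n * 300), n, 300)
  fit <- mass_univariate_regression(Y, cbind(x = rnorm(n)))
  tvals <- fit$t["x", ]
  ks <- ks.test(tvals, "pnorm")
  expect_gt(ks$p.value, 0.001)
})

test_that("regression is invariant to joint row permutation and rejects collinearity", {
  set.seed(3)
  n <- 100
  X <- cbind(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3)
  fit <- mass_univariate_regression(Y, X)
  perm <- sample(n)
  fit_p <- mass_univariate_regression(Y[perm, ], X[perm, ])
  expect_equal(fit$coef, fit_p$coef, tolerance = 1e-10)
  expect_error(
    mass_univariate_regression(Y, cbind(a = X[, 1], b = 2 * X[, 1])),
    "rank deficient"
  )
})

test_that("a global effect forms one full-span cluster at the minimal p", {
  set.seed(4)
  data <- matrix(5 + rnorm(12 * 40, 0, 0.5), 12, 40)
  res <- cluster_permutation_1d(data, n_perm = 500, seed = 1)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, 1)
  expect_equal(res$clusters$end, 40)
  expect_equal(res$clusters$p, 1 / 501)
})

test_that("sign-flipping the data flips cluster mass but not its p-value", {
  set.seed(5)
  data <- matrix(rnorm(10 * 60), 10, 60)
  data[, 20:30] <- data[, 20:30] + 1.2
  res_pos <- cluster_permutation_1d(data, n_perm = 300, seed = 2)
  res_neg <- cluster_permutation_1d(-data, n_perm = 300, seed = 2)
  expect_equal(res_pos$clusters$mass, -res_neg$clusters$mass)
  expect_equal(res_pos$clusters$p, res_neg$clusters$p)
})

test_that("the cluster test controls the family-wise error rate", {
  set.seed(6)
  n_rep <- 400
  fwer_hits <- vapply(seq_len(n_rep), function(i) {
    noise <- matrix(rnorm(10 * 30), 10, 30)
    res <- cluster_permutation_1d(noise, n_perm = 199, seed = i)
    nrow(res$clusters) > 0 && any(res$clusters$p <= 0.05)
  }, logical(1))
  rate <- mean(fwer_hits)
  # binomial s.e. at 400 repetitions is about 0.011
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.09)
})

test_that("the shuffle control detects own-regressor coupling and absorbs shared profiles", {
  set.seed(7)
  n_sub <- 8; n_t <- 300
  regs <- lapply(1:n_sub, function(i) rnorm(n_t))
  sigs <- lapply(1:n_sub, function(i) regs[[i]] + rnorm(n_t))
  res <- shuffle_control_z(sigs, regs, n_shuffle = 200, seed = 1)
  expect_gt(mean(res$z), 3)
  expect_lt(res$group$p, 0.01)

  # signals independent of every regressor: Z centred on zero
  sigs0 <- lapply(1:n_sub, function(i) rnorm(n_t))
  res0 <- shuffle_control_z(sigs0, regs, n_shuffle = 200, seed = 2)
  expect_lt(abs(mean(res0$z)), 1.5)

  # near-identical regressors across subjects: the coupling is carried by
  # the shared temporal profile, which the null absorbs, so Z stays small
  # even though every within-subject correlation is strong
  shared <- rnorm(n_t)
  regs_sh <- lapply(1:n_sub, function(i) shared + 0.1 * rnorm(n_t))
  sigs_sh <- lapply(1:n_sub, function(i) shared + rnorm(n_t))
  res_sh <- shuffle_control_z(sigs_sh, regs_sh, n_shuffle = 200, seed = 3)
  expect_gt(mean(res_sh$observed), 0.5)
  expect_lt(abs(mean(res_sh$z)), 1.5)
})

test_that("ridge decoding is exact in the noiseless low-penalty limit", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + 4
  res <- ridge_cv(X, y, penalty = 1e-8, n_folds = 20)
  expect_equal(res$rho, 1, tolerance = 1e-6)
  # infinite-penalty limit: predictions collapse to the training mean
  res_inf <- ridge_cv(X, y, penalty = 1e9, n_folds = 20)
  expect_lt(max(abs(res_inf$predictions - mean(y))), 0.05 * sd(y))
  expect_error(ridge_cv(X, y, penalty = -1), "non-negative")
})

test_that("ridge folds partition the rows and exclude the held-out fold", {
  n <- 57
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  res <- ridge_cv(X, y, penalty = 0.01, n_folds = 20)
  expect_equal(sort(unique(res$fold)), 1:20)
  expect_equal(tabulate(res$fold, 20), rep(c(3, 2), c(17, 3)))
  # held-out predictions differ from full-data fitted values (the model
  # that predicts a row never saw it)
  Xz <- apply(X, 2, zscore)
  full_pred <- drop(Xz %*% res$weights) + res$intercept
  expect_false(isTRUE(all.equal(res$predictions, full_pred)))
})

test_that("ridge weights match an independent ridge implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- drop(X %*% c(1, 0, -1, 2)) + rnorm(n)
  lambda <- 0.7
  res <- ridge_cv(X, y, penalty = lambda, n_folds = 10)
  Xz <- apply(X, 2, zscore)
  ref <- MASS::lm.ridge(y ~ Xz, lambda = lambda)
  # lm.ridge scales by n instead of n-1 internally; solve its normal
  # equations directly on the same standardized design for comparison
  w_ref <- solve(crossprod(Xz) + diag(lambda, 4), crossprod(Xz, y - mean(y)))
  expect_equal(unname(res$weights), drop(w_ref), tolerance = 1e-10)
  # direction agreement with MASS coefficients
  expect_gt(cor(unname(res$weights), unname(coef(ref)[-1])), 0.999)
})

test_that("ridge recovers a planted frequency-band loading", {
  set.seed(10)
  n <- 400
  freqs <- 6:40
  conf <- rnorm(n)
  feat <- matrix(rnorm(n * length(freqs)), n, length(freqs))
  band <- freqs >= 15 & freqs <= 20
  feat[, band] <- feat[, band] + 0.5 * conf
  y <- conf + rnorm(n, 0, 0.5)
  res <- ridge_cv(feat, y, penalty = 0.01, n_folds = 20)
  expect_gt(res$rho, 0.3)
  expect_gt(min(res$weights[band]), max(0, quantile(res$weights[!band], 0.75)))
})

test_that("group t-test statistics behave under sign flips and degeneracy", {
  set.seed(11)
  v <- rnorm(24, 0.3)
  a <- group_ttest(v)
  b <- group_ttest(-v)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$d, mean(v) / sd(v))
  expect_error(group_ttest(rep(1, 10)), "degenerate")
  # type-I calibration at alpha = 0.05
  rejections <- vapply(1:2000, function(i) {
    group_ttest(rnorm(24))$p < 0.05
  }, logical(1))
  expect_equal(mean(rejections), 0.05, tolerance = 0.4)
})
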