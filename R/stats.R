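#' One-sample group t-test with effect size
#'
#' @param values per-subject scalars (n >= 2, non-degenerate).
#' @return list with `mean`, `sem`, `t`, `p`, `d` (Cohen's d =
#'   mean / SD) and `ci` (95 percent confidence interval).
#' @export
group_ttest <- function(values) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) {
    stop("degenerate input: all values identical, t statistic undefined")
  }
  tt <- stats::t.test(values)
  list(
    mean = mean(values),
    sem = stats::sd(values) / sqrt(length(values)),
    t = unname(tt$statistic),
    p = tt$p.value,
    d = mean(values) / stats::sd(values),
    ci = unname(tt$conf.int)
  )
}

#' Mass-univariate multiple regression across timepoints
#'
#' Regresses the signal at every timepoint, across trials, on a common
#' design of z-scored predictors plus an intercept, and returns the
#' coefficient and t-value arrays. This is the per-subject first level
#' of a two-level analysis; feed the per-subject coefficient time
#' courses to [cluster_permutation_1d()] for the group level.
#'
#' @param Y trials x timepoints signal matrix.
#' @param X trials x predictors matrix or data.frame (z-scored
#'   internally unless `zscore_x = FALSE`; do not include an intercept).
#' @param zscore_x standardize the predictors? Disable to keep
#'   coefficients in the raw units of `X` (e.g. when comparing
#'   coefficients across trial binnings, where per-bin re-standardization
#'   would change the scale).
#' @return list with `coef` and `t` (predictors x timepoints matrices,
#'   intercept row included) and `df` (residual degrees of freedom).
#' @export
mass_univariate_regression <- function(Y, X, zscore_x = TRUE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  if (anyNA(Y) || anyNA(X)) stop("missing values are not allowed")
  Xz <- cbind(intercept = 1, if (zscore_x) apply(X, 2, zscore) else X)
  if (qr(Xz)$rank < ncol(Xz)) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(Xz, Y)
  coefs <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  df <- nrow(Y) - ncol(Xz)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(Xz))))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  list(coef = coefs, t = coefs / se, df = df)
}

# contiguous runs of same-signed supra-threshold t-values
find_clusters <- function(tvals, threshold, tail) {
  above <- if (tail == "two") abs(tvals) > threshold else tvals > threshold
  sgn <- sign(tvals) * above
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  }
  data.frame(
    start = starts[keep],
    end = ends[keep],
    mass = mapply(function(s, e) sum(tvals[s:e]), starts[keep], ends[keep])
  )
}

#' One-dimensional cluster-based permutation test
#'
#' Group-level correction for multiple comparisons along one axis
#' (typically time). Per timepoint, a one-sample t across subjects is
#' computed; contiguous supra-threshold runs of consistent sign form
#' clusters scored by their summed t-values. The null distribution of
#' the maximal cluster mass is built by randomly sign-flipping whole
#' subjects (the standard one-sample permutation scheme), and each
#' observed cluster gets p = (number of null maxima at least as large
#' + 1) / (n_perm + 1).
#'
#' @param subject_stats subjects x timepoints matrix (e.g. per-subject
#'   regression coefficients over time).
#' @param cluster_forming_p per-timepoint alpha defining the t threshold
#'   (two-tailed quantile for `tail = "two"`).
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param tail `"two"` (default) or `"one"` (positive direction).
#' @param seed integer seed for the permutation draws.
#' @return list of class `cluster_result` with `clusters` (start, end,
#'   mass, p), `threshold`, `n_perm`, `tail` and `t_obs` (the group
#'   t time course).
#' @export
cluster_permutation_1d <- function(subject_stats, cluster_forming_p = 0.05,
                                   n_perm = 1000, tail = c("two", "one"),
                                   seed = 1L) {
  tail <- match.arg(tail)
  subject_stats <- as.matrix(subject_stats)
  n_sub <- nrow(subject_stats)
  stopifnot(n_sub >= 2, n_perm >= 100)
  group_t <- function(M) {
    n <- nrow(M)
    m <- colMeans(M)
    v <- (colSums(M * M) - n * m * m) / (n - 1)
    m / sqrt(v / n)
  }
  threshold <- if (tail == "two") {
    stats::qt(1 - cluster_forming_p / 2, df = n_sub - 1)
  } else {
    stats::qt(1 - cluster_forming_p, df = n_sub - 1)
  }
  t_obs <- group_t(subject_stats)
  clusters <- find_clusters(t_obs, threshold, tail)

  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    t_p <- group_t(subject_stats * flips)
    cl <- find_clusters(t_p, threshold, tail)
    if (nrow(cl) == 0) 0 else max(if (tail == "two") abs(cl$mass) else cl$mass)
  }, numeric(1))

  if (nrow(clusters) > 0) {
    obs <- if (tail == "two") abs(clusters$mass) else clusters$mass
    clusters$p <- vapply(obs, function(m) {
      (sum(null_max >= m) + 1) / (n_perm + 1)
    }, numeric(1))
  } else {
    clusters$p <- numeric(0)
  }
  structure(
    list(clusters = clusters, threshold = threshold, n_perm = n_perm,
         tail = tail, t_obs = t_obs),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), |t| threshold %.3f, %d permutations (%s-tailed)\n",
              nrow(x$clusters), x$threshold, x$n_perm, x$tail))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Cross-subject shuffle control
#'
#' Tests whether a within-subject signal/regressor coupling survives
#' when the shared temporal profile of the regressor across subjects is
#' controlled for. The observed statistic is each subject's correlation
#' between their own signal and their own regressor; the null pairs each
#' subject's signal with regressors drawn from *other* subjects. Each
#' subject's Z is (observed - null mean) / null SD, and the group-level
#' test is a one-sample t on the Z values. A temporal profile common to
#' all subjects' regressors is absorbed by the null and yields Z near 0.
#'
#' @param signals list of per-subject signal vectors.
#' @param regressors list of per-subject regressor vectors (same order).
#' @param n_shuffle draws per subject from the other subjects'
#'   regressors.
#' @param seed integer seed.
#' @return list with `z` (per subject), `observed` (per-subject
#'   correlations) and `group` (see [group_ttest()]).
#' @export
shuffle_control_z <- function(signals, regressors, n_shuffle = 1000,
                              seed = 1L) {
  n_sub <- length(signals)
  stopifnot(n_sub >= 3, length(regressors) == n_sub)
  pair_cor <- function(x, y) {
    m <- min(length(x), length(y))
    stats::cor(x[seq_len(m)], y[seq_len(m)])
  }
  observed <- vapply(seq_len(n_sub), function(s) {
    pair_cor(signals[[s]], regressors[[s]])
  }, numeric(1))
  set.seed(seed)
  z <- vapply(seq_len(n_sub), function(s) {
    others <- setdiff(seq_len(n_sub), s)
    null <- vapply(seq_len(n_shuffle), function(i) {
      pair_cor(signals[[s]], regressors[[sample(others, 1)]])
    }, numeric(1))
    (observed[s] - mean(null)) / stats::sd(null)
  }, numeric(1))
  list(z = z, observed = observed, group = group_ttest(z))
}

# ridge solution with unpenalized intercept: center features and target
# within the training rows, penalize only the slopes
ridge_solve <- function(Xz, y, penalty) {
  xm <- colMeans(Xz)
  ym <- mean(y)
  Xc <- sweep(Xz, 2, xm)
  A <- crossprod(Xc) + diag(penalty, ncol(Xc))
  w <- drop(solve(A, crossprod(Xc, y - ym)))
  list(weights = w, intercept = ym - sum(xm * w))
}

#' Cross-validated ridge regression decoding
#'
#' Predicts a scalar target (e.g. a confidence report) from a feature
#' matrix (e.g. per-frequency power) with an L2-penalized linear model,
#' evaluated out of sample. Features are z-scored across rows; the
#' intercept is unpenalized. Folds are interleaved: row i belongs to
#' fold `(i - 1) mod n_folds + 1`, so every row is predicted exactly
#' once by a model that never saw it.
#'
#' @param features rows x features matrix.
#' @param target numeric vector, one value per row.
#' @param penalty non-negative ridge penalty on the z-scored features
#'   (default 0.01).
#' @param n_folds number of interleaved folds (default 20).
#' @return list of class `ridge_cv_result` with `predictions`
#'   (out-of-sample, aligned with rows), `rho` (Pearson correlation of
#'   predictions with the target), `weights` (full-data ridge weights
#'   per feature), `intercept` and `fold` (fold assignment).
#' @export
ridge_cv <- function(features, target, penalty = 0.01, n_folds = 20) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(target) == n)
  if (penalty < 0) stop("penalty must be non-negative")
  if (n < n_folds) stop("fewer rows than folds")
  Xz <- apply(features, 2, zscore)
  fold <- ((seq_len(n) - 1L) %% n_folds) + 1L
  predictions <- numeric(n)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    fit <- ridge_solve(Xz[!test, , drop = FALSE], target[!test], penalty)
    predictions[test] <-
      Xz[test, , drop = FALSE] %*% fit$weights + fit$intercept
  }
  full <- ridge_solve(Xz, target, penalty)
  structure(
    list(predictions = predictions,
         rho = stats::cor(predictions, target),
         weights = full$weights, intercept = full$intercept, fold = fold),
    class = "ridge_cv_result"
  )
}
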