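# cwlearn

Confidence-weighted learning of volatile transition probabilities: a
simulation and analysis toolkit for studying how a rational learner's
*confidence* shapes its belief updates, and how such latent variables
can be read out of single-trial physiological signals.

## What it does

The package implements, end to end:

1. **A volatile sequence task.** Binary tone sequences governed by
   first-order transition probabilities `(p(A|A), p(B|B))` that are
   resampled at unpredictable change points (per-trial probability
   1/75, uniform on [0.1, 0.9], at least a 4-fold odds change for one
   probability). Defaults: 24 subjects × 4 sessions × 380 trials, plus
   question schedules (median gap 13 trials, SD 4.4).
2. **A Bayes-optimal ideal observer.** A hidden-Markov forward
   recursion over a 20 × 20 probability grid with a flat prior. Per
   trial it emits the prediction `p` (posterior mean of the relevant
   transition probability), Shannon surprise `-log2 p(observed)`,
   confidence `-log var` (posterior log-precision of the relevant
   probability), and the Kullback–Leibler belief update.
3. **The latent-variable regression battery.** Update ≈ additive in
   surprise + confidence (pooled fitted-vs-actual Pearson ρ); the
   U-shaped dependence of confidence on `p`; the negative effect of
   previous surprise; the log-evidence-count effect; lag-1
   autocorrelations; residual (prediction-free) confidence.
4. **Synthetic single-trial signals** with known couplings to the
   latents — band power (confidence + AR(1) noise), evoked response
   (driven by surprise, suppressed by power, plus a *shared*
   measurement noise that creates a sign-opposed artifact), tonic and
   phasic pupil, and noisy bounded confidence reports.
5. **Inferential machinery**: mass-univariate regression,
   one-dimensional cluster-based permutation correction (sign-flip
   null, summed-t cluster mass), a cross-subject shuffle control, and
   interleaved cross-validated ridge decoding (penalty 0.01, 20 folds).

## Worked example

```r
library(cwlearn)

cfg <- task_config(seed = 11)   # 24 subjects x 4 sessions x 380 trials
battery <- run_behavioral_battery(cfg)   # ~3 s on one CPU
battery
```

```
Behavioral battery (Bayes-optimal observer)
  pooled trials: 36384
  update ~ surprise + confidence:        rho = 0.832
  update ~ surprise * confidence:        rho = 0.878
  confidence regressions (z-scored outcome), group mean +/- s.e.m.:
    beta_p2                      0.598 +/- 0.021  (t =  27.93, d =  5.70)
    beta_prev_surprise          -0.214 +/- 0.006  (t = -36.94, d = -7.54)
    beta_log_tsc                 0.258 +/- 0.011  (t =  23.19, d =  4.73)
    beta_prev_surprise_alone    -0.445 +/- 0.011  (t = -40.16, d = -8.20)
    beta_log_tsc_alone           0.358 +/- 0.008  (t =  45.36, d =  9.26)
    r_conf_p                     0.105 +/- 0.035  (t =   3.00, d =  0.61)
    r_adjacent_residual          0.609 +/- 0.012  (t =  51.31, d = 10.47)
    r_adjacent_raw               0.721 +/- 0.007  (t = 107.62, d = 21.97)
```

Reading this: belief updates are largely an additive function of
surprise and prior confidence (ρ = 0.83 between the two-regressor fit
and the actual KL update). Confidence is U-shaped in the probability
estimate (positive centered-`p²` weight, ≈ 0.60) while essentially
uncorrelated with it linearly (`r_conf_p` ≈ 0); it drops after
surprising tones (−0.21 per z-unit of previous surprise) and rises with
the log number of observations since the last change point; and it is
strongly autocorrelated across neighboring trials (0.72 raw, 0.61 after
removing all prediction-related components).

The binning demonstration — a true suppressive power→ERF coupling
hidden by a shared-noise artifact at bin size 1 and recovered at bin
size 10:

```r
s3 <- run_s3_experiment(task_config(n_subjects = 8, n_sessions = 1, seed = 77),
                        bin_sizes = c(1, 10))
s3
#>   bin_size power_coef    sem      t       p
#> 1        1      0.206 0.0091  22.66 8.3e-08   # artifact: wrong sign
#> 2       10     -0.178 0.0330  -5.41 1.0e-03   # true coupling emerges
```

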