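---
title: "Confidence-weighted learning of volatile transition probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted learning of volatile transition probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwlearn)
```

## The task and its generative model

A listener hears a long sequence of two tones, A and B. The sequence is
produced by first-order transition probabilities
$\theta = (p(A|A),\, p(B|B))$ that are *volatile*: on every trial there is
a small, fixed probability $p_c$ (default $1/75$) that both probabilities
are abruptly resampled — a change point. Resampling is uniform on
$[0.1, 0.9]$, constrained so that the odds of at least one of the two
probabilities change by at least a factor of 4
($\max_i |\log \mathrm{odds}_\mathrm{new} - \log \mathrm{odds}_\mathrm{old}|
\ge \log 4$); the constraint is enforced by rejection sampling. A session
is 380 tones; the default cohort is 24 subjects with 4 sessions each.
Occasional question trials (inter-question gaps drawn as
$\mathrm{round}\,\mathcal N(13, 4.4^2)$, truncated at 2) probe the
learner's probability estimate and confidence.

`task_config()` holds every constant; `generate_sequence()` and
`generate_question_schedule()` produce one session;
`simulate_task()` produces the whole cohort from a single master seed,
with per-cell child seeds spawned deterministically so any cell can be
regenerated in isolation.

## The Bayes-optimal ideal observer

The observer knows the generative model, including $p_c$, but assumes
resampling is uniform over the full unit square (it is unaware of the
$[0.1,0.9]$ bounds and the fold-change constraint). Because the
parameter pair evolves as "stay with probability $1-p_c$, redraw from the
prior otherwise", inference is a hidden Markov model forward recursion
over $\theta$: at each trial the current posterior is pushed through the
change-point kernel

$$p(\theta_{t+1} \mid y_{1:t}) = (1-p_c)\, p(\theta_t \mid y_{1:t}) + p_c\, \pi(\theta)$$

with $\pi$ the flat prior, then multiplied by the likelihood of the new
tone given the previous tone, and renormalized. Everything is computed
on a $20 \times 20$ grid (configurable) of *bin midpoints*
$(i-0.5)/n$, $i = 1..n$. Midpoints rather than endpoints keep every grid
value strictly inside $(0,1)$: no observation ever has zero likelihood,
surprise stays finite, and the posterior cannot collapse onto a
boundary cell of zero variance (with an endpoint grid the
log-precision diverges after long runs of one tone). Arithmetic is in
the linear domain with per-trial renormalization; the per-trial
normalization bounds the dynamic range, and the suite verifies absence
of underflow over long sequences.

Per trial the observer emits:

* **prediction** — the posterior mean of the *relevant* transition
  probability (the one conditioned on the most recent tone), mapped to
  the probability that the next tone is A;
* **surprise** — $-\log_2$ of the probability it had assigned to the
  tone that then occurred (bits);
* **confidence** — $-\log$ of the posterior variance of the relevant
  transition probability (natural log; log-precision). Confidence about
  a *prediction*, not probability of being correct;
* **KL update** — the divergence between the pre-observation belief and
  the posterior after the tone, the operational measure of belief
  revision.

Two timing conventions coexist and both are recorded by
`run_observer()`: the *prior* quantities at trial $t$ condition on tones
$1..t{-}1$ (these define surprise), and the *posterior* quantities
condition on tones $1..t$ (these are the model's answers to the task's
questions and are what the behavioral battery analyses). Trial 1 has no
conditioning tone: prediction $0.5$, surprise 1 bit, flagged and
excluded from regressions.

Two genuinely open choices are exposed as arguments rather than fixed:

* `kl_reference`: whether the "prior" of the update is the
  post-transition belief (default) or the previous trial's raw
  posterior;
* `kl_direction`: whether the update is
  $D(\mathrm{prior}\,\|\,\mathrm{posterior})$ (default) or the reverse.
  The default direction follows the usual reading of "divergence between
  the prior and the posterior" and is the one under which the pooled
  update regression below lands at $\rho \approx 0.836$; the reverse
  direction gives $\rho \approx 0.86$.

Correctness is anchored by two independent oracles in the test suite:
exact brute-force enumeration over all $2^{n-1}$ change-point
configurations for short sequences (max cell error $< 10^{-10}$), and
Beta-conjugate quadrature in the $p_c = 0$ limit (agreement to
$10^{-12}$).

## The latent-variable regression battery

`run_behavioral_battery()` simulates the default cohort
(24 × 4 × 380; about 2–3 s on one CPU), runs the observer, and computes:

* **Update additivity.** One pooled OLS of the KL update on z-scored
  surprise and z-scored prior confidence, with and without their
  product. The Pearson correlation between fitted and actual update is
  ≈ 0.83 without the interaction: belief revision is mostly an additive
  function of how surprising the tone was and how confident the
  observer already was — higher prior confidence, smaller update at
  matched surprise. A caveat this package makes explicit: the relation
  is very close to *log*-additive (regressing $\log$ KL on the same two
  regressors gives $\rho = 0.997$ with no interaction gain), so on the
  raw KL scale the interaction still adds about 0.04 of correlation
  here (≈ 0.88 with interaction).
* **The U-shape of confidence in $p$** (`beta_p2`). Per subject,
  z-scored confidence is regressed on the z-scored probability estimate
  and its *centered square* (the square of the z-scored prediction).
  The centered square isolates curvature; the raw square is nearly
  collinear with $p$ itself ($r \approx 0.95$), which makes the raw-square
  coefficient an unstable, inflated quantity (≈ 2.5 with a
  between-subject s.e.m. of 0.15). Group mean ≈ 0.59 ± 0.02: confidence
  is high when $p$ approaches 0 or 1, i.e. when the next tone is
  predictable either way — while the *linear* correlation between
  confidence and $p$ (`r_conf_p`) is ≈ 0.
* **Previous surprise and accumulated evidence** (`beta_prev_surprise`,
  `beta_log_tsc`). In a joint per-subject regression of confidence on
  $[p,\ p^2_\mathrm{centered},\ \text{previous-observation surprise},\
  \log N]$ (with $N$ the number of observations since the last true
  change point), the surprise weight is ≈ −0.21 ± 0.01 (surprising tones
  erode confidence) and the $\log N$ weight is ≈ 0.26–0.31 (confidence
  grows with accumulated evidence, approximately linearly in $\log N$
  within a stable stretch). Standalone single-predictor versions are
  reported alongside (`*_alone`); both outcome standardizations
  (z-scored and raw log-precision units) are computed.
* **Temporal smoothness** (`r_adjacent_residual`, `r_adjacent_raw`).
  Lag-1 autocorrelation of confidence within session: ≈ 0.72 raw, and
  ≈ 0.60 after residualizing out every prediction-related component
  (`residual_confidence()` removes $[p, p^2, \log p, \log(1-p)]$). The
  residual series is the one used as a regressor wherever a
  prediction-free confidence signal is needed.

## Synthetic neural and pupil signals

`simulate_power_erf()` implements a deliberately simple single-trial
generative model tying measurements to the latents (parameters are
illustrative, not fit to anything): band power is confidence plus AR(1)
noise (lag-1 autocorrelation 0.5, SD 1); the evoked response is driven
by surprise and *suppressed* by power
($\mathrm{ERF} = -(\beta_2\,\mathrm{SURP} + \beta_3\,\mathrm{POWER}) +
\varepsilon$, $\beta_1 = \beta_2 = 0.25$, $\beta_3 = 0.5$) — the
confidence-weighting prediction that a response to the same surprise is
weaker when the prior belief is more precise. Crucially, one shared
white-noise realization is added to *both* measured signals, emulating
trial-wise fluctuations in signal expression that inflate power and
response together. The true (negative) coupling and the (positive)
artifact therefore have opposite signs.

`run_s3_experiment()` turns this into the binning analysis: regress the
measured ERF on surprise, residual confidence and measured power, per
subject, after averaging runs of $k$ consecutive trials into
non-overlapping bins (trailing partial bins dropped so every bin
averages equally many trials; regressors kept in raw units so
coefficients are comparable across $k$). Unbinned, the artifact wins
and the power coefficient is *positive* (wrong sign, ≈ +0.2); with bins
of 10 the artifact — white at the trial timescale — averages away and
the coefficient approaches the true −0.5. Setting the shared noise to
zero removes the artifact at every bin size (coefficient = −0.5
exactly), and zeroing both gives a null coefficient: the three-way
dissociation the suite asserts.

`simulate_pupil()` couples tonic pupil size negatively to confidence
(AR(1) noise, lag-1 autocorrelation 0.75) and phasic dilation
positively to surprise (white noise); only the signs of the two gains
are constrained by theory, their magnitudes (−0.1, +0.2) are plumbing
defaults. `simulate_reports()` produces bounded confidence reports at
question trials as a logistic squash of scaled-plus-noisy optimal
confidence, with the gain calibrated by root finding on the realized
sample so that the report/confidence correlation hits its target
(default 0.23) — a self-calibrating construction, verified by its own
Monte-Carlo test.

## Inferential machinery

* `mass_univariate_regression()` — per-timepoint OLS across trials with
  a shared design (first level of a two-level analysis).
* `cluster_permutation_1d()` — group-level correction along one axis:
  per-timepoint one-sample t across subjects, contiguous same-signed
  supra-threshold runs scored by summed t, null distribution of the
  maximal cluster mass from whole-subject sign flips, and
  $p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n_\mathrm{perm} + 1)$ so
  p is never zero. Sign flipping is the standard one-sample scheme; the
  cluster-forming threshold is the two-tailed t quantile at the stated
  alpha with $n_\mathrm{subjects} - 1$ degrees of freedom. The suite
  verifies a family-wise error rate of ≈ 0.05 under the null by
  simulation.
* `shuffle_control_z()` — a conservative control for regressors whose
  temporal profile is shared across subjects (confidence is low after
  every session start, for instance): each subject's observed
  signal/regressor correlation is z-scored against a null built by
  pairing their signal with *other* subjects' regressors. A coupling
  carried by the shared profile yields Z ≈ 0; only subject-specific
  coupling survives.
* `ridge_cv()` — L2-penalized decoding with the penalty applied to
  z-scored features and an unpenalized intercept (features and target
  centered within the training rows), evaluated on interleaved folds
  (row $i$ → fold $i \bmod k$): every row is predicted exactly once by
  a model that never saw it. Default penalty 0.01, 20 folds. An
  independent implementation (`MASS::lm.ridge`) cross-checks the
  weights in the tests.

`run_decoding_experiment()` assembles these into the question-trial
decoding analysis: per-question multi-frequency "power" features (6–40
Hz) with a confidence loading planted at 15–20 Hz, noisy reports, ridge
decoding per subject, and a group test on the out-of-sample Pearson
accuracies. Feature noise is smooth across the frequency axis (AR(1),
coefficient 0.9) because neighboring band-power estimates are strongly
correlated in practice; with white features, 35 dimensions under a 0.01
penalty would be pure overfitting. Because reports carry only a 0.23
correlation with optimal confidence and the observer's confidence is
itself autocorrelated across questions, per-subject accuracies are
small (group mean ≈ 0.01–0.07 with per-subject SD ≈ 0.1) and an
unpaired group test at $n = 24$ hovers around the significance
boundary — which is also the regime the original analysis reports. The
stable property, asserted in the tests, is the paired contrast against
the identical cohort with no planted loading (t ≈ 5–9), plus the
concentration of the full-data ridge weights in the planted band.

## Numerical and design notes

* Tones are integers (A = 0, B = 1); all randomness flows from explicit
  seeds, and every generator is byte-reproducible given its seed.
* The rejection sampler for change-point resampling caps retries at
  10⁴ and errors beyond it (an infeasible fold-change constraint).
* `bin_trials()` drops trailing partial bins so every bin has equal
  noise variance; binning never crosses a session boundary, and neither
  do lag-1 pairs or lagged regressors.
* Degenerate inputs error loudly: zero-variance vectors in `zscore()`
  and `group_ttest()`, rank-deficient designs, posterior underflow,
  support mismatches in the KL, sub-100-trial update regressions.
  `run_behavioral_battery()` converts these to warnings plus an
  `underpowered` flag so a degenerate scale still returns.
* Problem sizes in the tests: the full 24 × 4 × 380 battery runs once
  (≈ 3 s); the enumeration oracle uses sequences of ≤ 12 trials on
  grids ≤ 11; the family-wise-error simulation uses 400 replications
  of 10 × 30 datasets at 199 permutations; decoding checks use the
  default cohort. These sizes keep every Monte-Carlo tolerance at
  ≥ 3 standard errors.

## What the synthetic data does and does not show

The task generator *is* the study's generative process, so
model-internal quantities (the regression battery above) are estimated
under the exact conditions that produced the original model-side
numbers, and agreement there is meaningful. The neural/pupil/report
simulators, by contrast, are intentionally minimal linear-Gaussian
stand-ins: passing their tests shows that the statistical machinery
detects exactly the planted structure (signs, couplings, artifact
suppression), not that real MEG or pupil data behave this way. Known
limitations: no sensor geometry or spatial correction (the cluster test
is 1-D), no hierarchical inference over $p_c$, no modeling of subjects'
deviations from Bayes-optimality, and two printed quantities that do
not reproduce under any convention we tried — the log-observation-count
weight (we find ≈ 0.26–0.31 vs the printed 0.16) and the near-zero gain
of the surprise-by-confidence interaction on the raw-KL scale (we find
+0.04) — both documented in the battery output rather than hidden.
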