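---
title: "Gaze-strategy analysis for matrix reasoning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-strategy analysis for matrix reasoning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gazestrat)
library(dplyr)
```

## The problem

When people solve matrix reasoning items (a 3×3 problem grid with a bank of
eight answer choices), their eye movements betray *how* they solve them.
Two idealized strategies anchor the literature: **constructive matching**
(mentally build the missing cell, then check the answers — long matrix
dwell, few gaze "toggles" between matrix and answers) and **response
elimination** (repeatedly compare answer candidates against the matrix —
many toggles). In practice pure elimination is rare; the second recurring
pattern is a *hybrid* scan that still walks the matrix but enters the
answer bank from any row.

`gazestrat` turns fixation-event exports into:

1. fourteen participant-level gaze metrics,
2. a two-cluster strategy classification of every trial's scanpath,
3. LASSO models predicting cognitive scores from the metrics,
4. comparisons of dependent correlations (Steiger's z) and Bayes-factor
   cluster contrasts,

plus a synthetic study generator so every stage can be exercised, tested
and calibrated with no external data.

## Preprocessing

Fixations are tagged with the AOI containing their coordinates. AOI
rectangles are half-open, `[x0, x1) × [y0, y1)`, so shared edges are
unambiguous and tagging is a pure function of the coordinates. Three
filters then apply, in this order:

* the **first fixation of every trial** is dropped unconditionally (it
  reflects the preceding fixation cross, not the item);
* fixations **outside every AOI** are dropped;
* fixations shorter than the **minimum duration** (default 100 ms) are
  dropped. The rule is inclusive (`>= 100`) because recorders typically
  enforce a 100 ms minimum event duration, so a strict `>` would drop
  boundary events erratically; `strict = TRUE` switches the convention.

Participant-level quality control excludes participants with fewer than 3
raw fixations per trial on average (the "two or fewer" rule), a validity
ratio below 0.5, or any score beyond 3 SD of the cohort mean. The 3-SD
rule is applied per score column on the cohort that survives the
gaze-quality rules, and a zero-SD column excludes nobody. The validity
ratio uses a recorder-reported tracking ratio when one is supplied; when
it is not, the fraction of trials with a non-empty filtered scanpath
stands in, and the QC report labels the source. The published exclusion
threshold ("50% valid data") does not state its denominator, so both
interpretations are exposed rather than asserting either.

## The fourteen gaze metrics

`compute_gaze_metrics()` returns, per participant: average item time (s);
matrix–matrix, matrix–answer and answer–answer transition totals; latency
to the first answer fixation (ms); the matrix/answer dwell-time ratio;
mean visits per matrix cell and per incorrect answer choice; fixation
counts and mean fixation durations on each side; the percentage of trials
classified as cluster 2; and the matrix–answer transition rate per second.

Published tables mix "number of…" and "average…" phrasing without fixing
the aggregation level, so the package adopts one convention and holds it
everywhere — the *totals convention*: transition and fixation counts are
totals over the scored trials; time-type metrics are per-trial (or
per-fixation) means; visit metrics are means per cell (or per incorrect
choice) per trial; the dwell ratio is total matrix dwell over total answer
dwell. The convention makes the transition rate exactly self-consistent:

```{r identity}
st <- simulate_study(synth_config(n_participants = 6, seed = 1))
m <- st$truth$metrics
all.equal(m$ma_transition_rate_per_s * m$avg_item_time_s * m$n_trials,
          as.numeric(m$n_ma_transitions), tolerance = 1e-9)
```

A "visit" is one maximal run of consecutive fixations in the same AOI, so
visit counts equal occurrence counts in the collapsed sequence. Transition
metrics are computed on the collapsed sequence, consistent with the
clustering representation. Trial duration is the last retained fixation's
offset (response timestamps are not part of fixation exports; this is an
approximation of the recorder's trial time, and is flagged as such).
Degenerate denominators — a participant who never fixates an answer —
produce `NA`, never infinities; the modelling layer drops and logs such
participants.

## Scanpath clustering

Each trial's collapsed scanpath becomes a 10×10 transition probability
matrix over 9 matrix cells plus the answer bank *pooled as one AOI* (the
cluster portraits in this literature concern row/column structure within
the matrix, not individual choices; per-choice granularity is available
via the 17-AOI sequence utilities). Rows with no outgoing transition stay
all-zero — a uniform row would fabricate transitions never observed. The
90 off-diagonal entries form the feature vector.

Two-centroid k-means (within-cluster sum of squared Euclidean distances)
classifies all trials. Initialization is a seeded farthest-point rule with
25 restarts, keeping the lowest objective (ties to the earliest restart),
which makes fits deterministic given a seed; for 12 or fewer scanpaths
the objective is instead minimized exactly by enumerating bipartitions,
since Lloyd iterations can stall in local optima that enumeration rules
out at negligible cost. Because k-means labels are
arbitrary, labels are **canonically oriented**: cluster 2 is the cluster
whose centroid carries more total transition mass into the answer region —
the hybrid, answer-oriented strategy — so "percent cluster 2" means the
same thing across runs and seeds.

Cluster contrasts use a two-sample Jeffreys–Zellner–Siow Bayes factor
(Cauchy prior on the standardized difference, scale $\sqrt{2}/2$),
computed by adaptive quadrature on the one-dimensional g-mixture integral.
Contrasts are run at the *trial* level, because clusters are trial-level
objects; the participant-level alternative can be had by aggregating
per-participant means first. Evidence categories follow the 3 / 10 / 100
thresholds and their reciprocals.

## Predictive models

For each requested score, the pipeline: (1) splits participants into
train/test parts (default 80/20 by `round(0.8 n)`, seeded); (2) z-scores
predictors and response using *training* statistics only, so no test
information leaks into the standardization (a flag for whole-sample
scaling exists for comparison runs); (3) selects the L1 penalty by
leave-one-out cross-validated RMSE over a 100-point log-spaced grid from
the analytic threshold $\lambda_{max} = \max_j |x_j^\top y| / n$ down to
$10^{-4}\lambda_{max}$, ties broken toward the larger penalty; and (4)
reports test-set r, $R^2 = 1 - SS_{res}/SS_{tot}$, MAE and RMSE. With a
standardized response the errors are in SD units, and $R^2$ may be
negative when predictions are worse than the test mean — that outcome is
reported, not clipped.

The solver is cyclic coordinate descent with soft-thresholding on the
covariance form of the objective, warm-started along the penalty path
(compiled, with a pure-R reference implementation that the test suite
cross-checks, alongside an independent `glmnet` comparison). Convergence
is declared when the largest coefficient change in a sweep falls below
1e-8. The sweep cap (10^5; 10^3 inside cross-validation folds) is a
stopping rule rather than an error: among strongly collinear predictors
the split of weight between near-duplicate columns converges arbitrarily
slowly along a direction that leaves predictions unchanged, so fold
predictions — the only thing the folds contribute — are stable orders of
magnitude before the coefficient tolerance is met.

## Dependent correlations

Steiger's test compares the correlations of one gaze metric with two
different cognitive tests measured in the same sample: Fisher-z transforms
of the two correlations, an asymptotic z with the Dunn–Clark covariance
for correlations sharing one variable, evaluated at the individual sample
correlations. In sign-ignored mode (the default) the two compared
correlations enter as absolute values — the test then compares *strengths*
of association — while the test–test correlation stays signed. This
variant reproduces the one worked value recomputable from published
inputs:

```{r steiger}
steiger_test(r_jk = -0.37, r_jh = 0.03, r_kh = 0.16, n = 69)
```

Forest-plot data use the Fisher interval
$\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$.

## The synthetic study generator

`simulate_study()` emits a complete study — fixation table, AOI layout,
item key, score table — plus the planted ground truth. Its defaults *are*
the study conditions the rest of the package is tested under: 60
participants, 18 scored and 3 practice trials, ~30 AOI entries per trial
(negative binomial), lognormal fixation durations (median 260 ms matrix /
230 ms answers, truncated at the 100 ms recorder floor), and 5% injected
noise fixations (half sub-threshold, half outside every AOI) so the
preprocessing filters always have work to do.

Two hand-authored Markov kernels embody the strategies: the constructive
kernel walks rows left-to-right and enters the answers almost only after
the bottom row; the hybrid kernel mixes row and column moves and enters
the answers from any row end with much larger total entry mass. A
`separability` knob interpolates the hybrid kernel toward the constructive
one: at 0 the strategies are identical and clustering agreement must fall
to chance; at the default 1 the two-cluster fit recovers planted
trial-level strategies with ≥95% agreement. Each participant draws a
hybrid-strategy propensity from Beta(12, 12); each trial flips that coin.
Strategy use is thus mostly a trial-level phenomenon with moderate stable
individual differences, which matches the view that item characteristics,
not fixed styles, drive strategy choice.

The stimulus geometry is a *synthetic stand-in* (the original apparatus
geometry is unpublished): a 3×3 grid on the left and a 2×4 answer bank on
the right of a 1680×1050 px screen, with non-overlapping half-open
rectangles.

### Identifiability by design

Scores are noisy linear functions of standardized true metrics; the
default `reasoning` score loads on exactly three metrics (matrix–answer
transitions −0.45, dwell ratio +0.45, wrong-answer visits −0.45) with
noise calibrated so the linear predictor explains 60% of score variance.

For a support-recovery benchmark to be meaningful, those three metrics
must be *identifiable*, and the 14-metric set makes that genuinely
delicate: it contains near-exact internal identities. Scanpath
combinatorics force matrix–answer transitions ≈ 2 × (matrix visits −
matrix–matrix transitions) up to per-trial boundary terms; under the
totals convention the dwell ratio is exactly the product/quotient of the
per-side mean fixation durations and fixation counts; and the transition
rate times item time times the trial count reconstructs the transition
total. An L1 selector will happily represent a planted signal through
such a substitute whenever the substitute is cheap in penalized
coefficient mass. The generator is therefore designed so each planted
metric carries a dominant trait of its own while its substitutes are
L1-expensive:

* **transitions** — strategy propensity is narrow (Beta(12, 12)) and the
  chain-mean spread small (sdlog 0.1), so answer-entry totals are
  dominated by idiosyncratic trial noise whose only exact substitute
  (the visits-minus-transitions identity) leaves an unexplained
  boundary-term residual;
* **dwell ratio** — independent lognormal spreads of matrix-side (0.35)
  and answer-side (0.40) fixation-duration levels feed the ratio but not
  the count metrics, and wide within-AOI refixation-run traits (sdlog
  0.7; invisible to the clustering features, which collapse repeats)
  make the fixdur × count decomposition of the ratio expensive;
* **wrong-answer visits** — a correct-answer *focus* trait (sampling
  weight of the correct choice during answer browsing, lognormal around
  4 with sdlog 1.4), so efficient-looking participants park answer gaze
  on the correct choice and rack up few wrong-answer visits without
  changing transition or browse counts;

plus a **deliberation** trait (sdlog 0.4) that divides the kernels'
answer-entry mass and lengthens the chain by the same factor — deep
matrix scanning per answer check — so matrix-side visit and transition
counts vary across participants while answer entries do not.

These are properties real cohorts show in kind (individual differences
in fixation duration, re-fixation habits, scanning depth and answer
focus are all documented), though the generator's independence structure
is cleaner than reality: passing the recovery suite demonstrates the
pipeline works where the signal is identifiable, not that real gaze
metrics are this well separated — published correlation matrices in this
literature put some metric pairs above 0.9, where no selector can
distinguish them.

## Numerical and degenerate-input choices

* Collapsing, tagging and filtering are deterministic; every stochastic
  stage (generator, splits, clustering restarts) consumes an explicit
  seed, and reruns are byte-identical.
* Clustering with all-identical feature vectors returns a degenerate
  one-cluster model with a warning rather than an error.
* Skewness and excess kurtosis use the bias-corrected sample estimators
  (normal ⇒ 0/0); constant columns report `NA` with a reason.
* Correlation matrices use pairwise-complete observations with the
  per-pair n recorded; derived tests use the minimum involved n.
* `|r| = 1` inputs to Fisher-transform machinery are errors (the
  transform diverges), as are Steiger tests with n < 4.

## Problem sizes used by the test suite

The bundled checks run the generator at its default study size (60 × 21
trials, ~50k fixations) for the clustering and recovery benchmarks, 50
seeded replicates for support recovery, 10,000 replicates for the
Steiger type-I calibration, and 10,000 randomized cases per structural
identity. Unit tests use a 10-participant configuration of the same
generator.

## Limitations

* The generator does not model oculomotor dynamics (saccade amplitudes,
  drift, microsaccades), item difficulty, learning across trials, or
  response times; nothing here validates metrics against those phenomena.
* The clustering granularity (pooled answer AOI) and the trial-level unit
  for Bayes-factor contrasts are documented package choices where the
  literature is silent; both have exposed alternatives.
* LASSO coefficients are reported without inference (no CIs or p-values);
  selection is conditioned on the data and should be read as exploratory.
* Test-set estimates at n≈12 are noisy; negative R² values are expected
  behavior for weak models, not errors.
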