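---
title: "Predicting negative emotions from phone usage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting negative emotions from phone usage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodphone)
```

`moodphone` turns passively logged phone usage into personalized
predictions of three momentary negative emotions (depression, anxiety,
stress, each reported on a 0–100 visual analog scale). This vignette
explains the models, the tunable parameters, the synthetic data the
package tests itself against, and the design decisions taken where the
procedure was genuinely open.

## From polled samples to usage events

The raw log is a pair of sample streams polled every `sample_period`
seconds (default 3 s): the telephony call state (`idle`, `ringing`,
`offhook`) and the package name of the app on screen. Events are maximal
runs of identical samples, with three conventions:

* **Closing-sample rule.** A sample is the left endpoint of a
  `sample_period`-second occupancy interval, so a run ends at its last
  sample plus one period. Without this, single-sample events would have
  zero duration. All intervals are half-open `[start, end)`.
* **Gap rule.** A gap greater than `2 * sample_period` between
  consecutive samples closes any open run at the last seen sample. This
  tolerates exactly one dropped poll, a deliberate robustness choice for
  polling jitter; nothing in the data model says how often real loggers
  drop samples.
* **Call semantics.** `ringing … → idle` is a missed call spanning the
  ringing run; `ringing … → offhook` is an incoming call starting at the
  first off-hook sample (ringing time is excluded from call duration, and
  the ringing span of an answered call is not emitted as an event of its
  own); `idle → offhook` is an outgoing call. App sessions are runs of
  one package; their union, merged across gaps of at most
  `2 * sample_period`, is screen usage. The two channels are treated as
  independent: the data model has no way to express how a call and an
  on-screen app interact.

The test suite validates this run-length inference against an independent
per-second reconstruction (explicit state expansion second by second) on
hundreds of randomized streams.

## Windowed features

For an emotion tag at time *t* and a timeslot width *w* ∈ {0.5, 1, 1.5,
2} h, every usage type (the three call types, screen usage, each of the
user's top-10 apps by total foreground time, each observed app category)
contributes four statistics over `[t − w, t)`: count, total duration,
average duration, and the average interval between the start of one event
and the end of the previous event of the same type.

Degenerate-input decisions, all chosen to keep the design matrix dense
and classifiers well-defined: an empty window contributes 0 for every
statistic; a single event has `average_interval = 0` (no pair exists);
events straddling the window boundary are *clipped* rather than excluded,
because duration statistics should reflect in-window usage only;
`average_interval` uses only event pairs resolved within the window.
Zero-variance columns are retained but flagged — dropping them is the
feature-selection methods' job.

## Category structure

The VAS range is divided into three equal-width ordered categories:
low < 100/3 ≤ medium < 200/3 ≤ high, with cut points belonging to the
upper category. Fixed equal thirds (rather than per-user empirical
tertiles) are used because the evaluation phase must categorize
predictions before any evaluation data has accrued. Users need at least
40 training tags to be modeled at all.

## Feature selection

The three categories are reduced to two binary "levels": level 1 is
low vs {medium, high}, level 2 is {low, medium} vs high. These groupings
are an assumption (the split into levels is fixed, its exact composition
was an open design point) and are isolated in one place
(`two_level_split()`).

* **Welch filter** (`ttest_select`): a feature is chosen if its
  unequal-variance t-test P value is below .05 at either level; if fewer
  than five features are chosen, the smallest min-over-levels P values
  fill the set to five.
* **Homoscedastic filter** (`ttest_homoscedastic_select`): pooled
  variance t tests; every feature starts chosen and features with P < .05
  at either level are deleted — here a small P flags the feature as
  unstable across the category split. If deletion empties the set, the
  five largest-P features are retained.
* **Greedy wrappers** (`greedy_select`): forward, backward and
  bidirectional best-first search over feature subsets. The scorer is
  stratified 5-fold cross-validated accuracy of a **fixed Gaussian
  naive-Bayes classifier** with a fixed fold seed. The scorer family was
  an open choice; fixing it makes the selected subset a property of the
  (user, scale, timeslot, method) context — shared across the four
  classifier families exactly as the filter selections are — and admits a
  fast exact implementation: per fold and class, per-feature Gaussian
  log-densities of the held-out rows are precomputed once, so scoring any
  subset is a column sum plus an argmax. A strict improvement
  (> 10⁻¹²) is required to continue; ties among candidate features break
  by column order; each subset is evaluated at most once (memoized).

Features with an undefined t statistic (no variability) are never
auto-selected and never deleted. No multiple-testing correction is
applied — the filters are deliberately liberal per-feature screens.

## Classifier families

All four families sit behind one train/predict contract and predict only
categories seen at training; single-class training data yields a constant
predictor with a warning.

* **Gaussian naive Bayes** — written in-package (class-conditional
  Gaussians with per-feature variance smoothing of
  `1e-9 * max(pooled variance, 1)`), because it is also the wrapper
  scorer and the NBTree leaf model and must be fast; the test suite
  cross-checks its predictions against `e1071::naiveBayes`.
* **C4.5-style tree** — `rpart` with information-gain splits,
  `minsplit = 5`, and cost-complexity pre-pruning at `cp = 0.01` standing
  in for C4.5's error-based pruning.
* **NBTree** — bespoke: a shallow tree (depth ≤ 3, minimum node 10)
  whose leaves hold naive-Bayes models. The candidate split is a
  threshold at the median of the feature with the largest
  between/within-class variance ratio, and it is accepted only if the
  size-weighted 3-fold cross-validated accuracy of the children's leaf
  models beats the node's own cross-validated leaf accuracy. Restricting
  the split search to this single screened candidate keeps the model
  cheap enough to refit hundreds of times inside cross-validation.
* **SVM** — `e1071::svm`, RBF kernel, cost 1, median-heuristic kernel
  scale (γ = 1 / (2 · median pairwise squared distance)), on internally
  standardized features. Multi-class handling is e1071's pairwise voting.

Hyperparameters are fixed at these conventional defaults; the procedure
compares *families*, not tuned models.

## Combination selection

Every (timeslot, selection method, family) triple is one candidate
detection classifier: 4 × 5 × 4 = 80 per user and scale, each scored by
stratified 5-fold cross-validated accuracy on identical folds within a
(user, scale, timeslot) context (wrapper combinations reuse the search's
own best score, which is the same cross-validation). Selection happens in
two stages:

1. per selection method, (timeslot, family) pairs are ranked within every
   (user, scale) context by accuracy (rank 1 best, ties share the average
   rank, a failed combination takes the worst rank) and aggregated by the
   geometric mean of ranks — the geometric mean rather than the raw
   product so scores are comparable across context counts;
2. among the five per-method winners, the deployed combination maximizes
   mean accuracy over the three scales averaged over users.

Ties break toward the smaller timeslot, then name order. Contexts are
(user × scale) rather than users only — another open point, resolved in
favor of more contexts for the rank aggregation. One model is trained per
(user, scale) on that scale's selected features.

## Evaluation protocol

The deployed model predicts every 2 hours from 11:00 to 23:00. A
responded prediction succeeds only if all three corrected ratings land in
the predicted categories. Per-user accuracy is 100 × successes /
responses, rounded half-up to 2 decimals (half-up, not R's banker's
rounding, to match conventional table presentation). The cohort accuracy
is the **unweighted mean of per-user accuracies** — this, not the pooled
successes/responses ratio, is the headline statistic; both are reported
and labeled. Users with zero responses are excluded from the mean with a
warning.

Two benchmarks run on the same responded predictions: per-scale ordinary
least squares on the raw VAS values (predictions clipped to [0, 100] and
categorized; rank-deficient designs fall back to pivoted least squares
with a warning), and the "general guess", interpreted as always
predicting the user's most frequent training category per scale (ties to
the lower category). "General guess" had no operational definition; the
majority-category reading is logged as an assumption.

## The synthetic cohort

`simulate_user()` emulates the study conditions: 14 training days with 4
tags/day at least 3 h apart, then 5 evaluation days with responses on the
7-per-day schedule (response probability 0.987). Usage is a marked point
process over a 08:00–24:00 waking window — Poisson call arrivals with
per-user incoming/outgoing rates (~0.25–0.3/h), log-normal call and app
session durations, a renewal process of app sessions (~2/h) over a
per-user Dirichlet app preference — the simplest processes that give all
four statistics non-degenerate values. These distributional choices are
conventions, not estimates from any real cohort.

Each tag's three VAS values are `50 + effect_size · z + noise`, where `z`
is the standardized sum of planted features (defaults: screen total
duration, outgoing-call count, social-category total duration) computed
over the **2-hour** window preceding the tag, normalized so that
`effect_size` is the systematic standard deviation in VAS points;
`noise_sd` (default 10) is Gaussian, and values are rounded and clipped
to [0, 100]. `effect_size = 0` severs the usage-emotion link entirely.
The VAS range 0–100 in integer steps is itself a convention.

Two generator implementation details matter for testing. Event times are
quantized to the polling grid and episodes are separated by more than two
polling periods, so inference from the emitted samples reconstructs the
generated events *exactly* — the round trip is asserted, not approximate.
And the raw stream is run-length suppressed (samples are emitted only
during call episodes and app sessions, with bracketing idle samples):
under the gap-closure rule this is observationally equivalent to
continuous polling while keeping files two orders of magnitude smaller.

What passing tests do and do not show: the synthetic cohort has a
stationary, linear, single-window dependence and honest reporting; real
usage is non-stationary (usage drift degrades a frozen personalized
model), effects need not be linear in these statistics, users may switch
devices, and suggestible users may agree with whatever is predicted.
Recovery of the planted 2-hour timeslot and a large margin over the
guess benchmark on this cohort validate the machinery, not the
psychology.

## Problem sizes and determinism

All randomness flows from one master seed through string-tagged 32-bit
sub-seeds, so users are independent and order-insensitive and every stage
is reproducible bit for bit (asserted by rerun tests). The test suite
sizes its Monte-Carlo checks as follows, chosen to make each statistical
assertion sharp at small scale: oracle equivalence on 50 × 200-sample
streams; timeslot recovery and benchmark margins on 20 replicate cohorts
of 10 users (10 training days, `effect_size = 30`, `noise_sd = 5`, a
6-app catalog, the 4 timeslots with the Welch filter and forward wrapper
over naive Bayes); the null-effect control on one 6-user cohort compared
at 3 binomial standard deviations; and one full 80-combination grid at
the canonical 56 training tags.

## Known limitations

* The two-level groupings, the equal-thirds categorization and the
  majority-category guess benchmark are documented assumptions where the
  procedure was underdetermined; all are isolated behind single
  functions.
* The C4.5 stand-in uses cost-complexity rather than error-based pruning,
  and the SVM uses pairwise voting rather than one-vs-rest.
* `average_interval` between events of one type is ill-defined across a
  window boundary; only pairs fully resolved in-window contribute.
* The generator does not model notification compliance psychology,
  multi-device users, circadian usage structure beyond the waking window,
  or non-stationary usage drift.
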