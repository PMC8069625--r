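---
title: "Classifying human wear and delivery days in mailed-accelerometer studies"
author: "wearday package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying human wear and delivery days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological studies frequently mail activity monitors to participants.
The device is activated before shipping and deactivated after return, so the
recorded stream contains days of postal transit — near-silent stretches
punctuated by brief handling and transport jolts — on both sides of roughly a
week of human wear. Before any physical-activity analysis those delivery
days must be removed, a task traditionally done by hand from mail logs and
plots. `wearday` automates it: every calendar day of an epoch-level
tri-axial count recording is classified as *human wear* (label 0) or
*delivery* (label 1, the positive class).

## Data model and processing

Input is a timestamped stream of nonnegative activity counts per axis at a
fixed epoch (60 s natively; finer resolutions are summed into wall-clock
minutes by `collapseToMinute()`, which conserves per-axis totals). The
stream is segmented into midnight-aligned days of exactly 1440 minutes
(`segmentDays()`). Because activation and deactivation rarely fall on
midnight, the first day is zero-padded from midnight to activation and the
last from deactivation to the following midnight; interior gaps are treated
as data corruption and rejected at read time rather than silently filled.

Two processing levels are offered:

* **minimal** — zero-padding only;
* **full** — padding plus removal of days that carry little information or
  indicate non-adherence: any day with fewer than 5000 total
  vector-magnitude counts, any day with fewer than 10 minutes of movement,
  and any *wear-labeled* day with fewer than 120 active minutes.

Three conventions here were genuinely open and are fixed as follows. A
"movement" minute is one with vector magnitude strictly greater than zero —
no threshold is defensible without device-specific calibration, and zero is
dialect-free. The 5000-count rule is evaluated on the vector-magnitude
series (the `statistic = "axis_sum"` option evaluates it on the sum of the
three axis totals instead, since either reading is plausible). Padded
minutes are excluded from all filter quantities, so padding can neither
rescue nor doom a boundary day. Rules are tested in the order
total-counts, movement, adherence, and the first rule to fire is the one
reported in the removal report.

## The eight day-level features

Feature models see each day through eight statistics of its 1440-point
vector-magnitude series `v`: mean, variance, maximum, 95th percentile,
absolute energy `sum(v^2)`, absolute change `sum(|v[i+1] - v[i]|)`,
kurtosis and skewness. Conventions, covered by brute-force oracle tests:
variance is the biased (divide-by-*n*) central moment; skewness is
`m3 / m2^1.5`; kurtosis is `m4 / m2^2` without the −3 excess correction
(set `excessKurtosis = TRUE` for the excess variant); a constant series has
skewness and kurtosis 0; the percentile interpolates order statistics
linearly (type 7 — alternative rules differ only in the fourth decimal on
1440 points and are selectable). Padded zeros are *included*: the feature
models must see a truncated boundary day exactly as the raw-input networks
do, which receive the zero-padded array.

Features and raw arrays are mean-centered and scaled by standard
deviations. The scaler is always fitted on the training split only and
stored inside the fitted model, so held-out days are transformed with
training parameters; a zero-variance feature gets scale 1, mapping it to
all zeros rather than NaN.

## Model families

Seven classifiers share one `fitModel()` / `predictProb()` contract.

**Feature-input.** The random forest uses 500 trees, minimum terminal node
size 1, Gini splits, and `floor(log2(p))` candidate features per split
(3 for the 8 features). The logistic regression expands every feature with
a 3-knot restricted cubic spline — the truncated-power natural-spline
basis, linear beyond its boundary knots, contributing two design columns
per feature — with knots at the 0.1/0.5/0.9 training quantiles, the
standard placement for three knots. Fitting is by iteratively reweighted
least squares with a mild ridge stabilizer (`1e-6`, unpenalized intercept;
0 recovers pure maximum likelihood, and the ridge-free fit is verified
against `stats::glm` in the tests). The mixed-effects variant adds a
participant random intercept via `lme4::glmer` (Laplace approximation);
held-out participants are by construction absent from training, so their
predictions use the population (fixed-effects) predictor — the random
intercept of an unseen participant is its prior mean, zero. The multilayer
perceptron stacks ReLU layers of 32 and 16 units on the scaled features.

**Raw-input.** The convolutional, recurrent, and convolutional-recurrent
networks consume the per-axis standardized 1440-by-3 day arrays. All train
with binary cross-entropy and Adam (learning rate 0.001) for 10 epochs at
batch size 32, deterministically under the model seed. The layer stacks
are configurable; the defaults are sized for day-level count data, where
the delivery/wear contrast is carried by coarse activity structure rather
than fine waveform detail:

* `cnn`: three same-padded conv blocks (8, 16, 16 filters, kernel 7) with
  max-pooling 4, 4, 2, global average pooling, sigmoid head;
* `rnn`: an LSTM of 32 units over the full 1440-step, 3-channel sequence;
* `crnn`: two conv blocks (8, 16 filters, pooling 4, 4) reducing the
  sequence 16-fold before a 32-unit LSTM — the convolutions compress the
  day so the recurrent layer processes 90 steps instead of 1440.

The training engine (dense, 1-D convolution via im2col, max pooling,
LSTM, Adam) is implemented in the package with C++ kernels for the
convolution gather/scatter; its backward pass is verified against finite
differences for every layer type in the test suite, which is the property
that matters for trusting the fits.

Each day is classified independently; the package deliberately does not
run recurrence across consecutive days of an assessment, which would blur
assessment boundaries. Hard labels use a 0.5 probability threshold
(configurable) wherever a threshold is needed.

## Cross-validation and metrics

Model evaluation uses five-repetition Monte Carlo cross-validation grouped
by participant: each repetition independently samples 30% of participants
as the test set and trains on the other 70%, so all assessments and days
of a participant travel together and no participant ever straddles the
boundary. Repetition seeds derive from a master seed. Reported metrics,
with delivery as the positive class: sensitivity TP/(TP+FN), positive
predictive value TP/(TP+FP), their harmonic mean F1, and the Brier score
— the mean squared difference between forecast probability and outcome. A
repetition whose metric denominator is empty is reported as missing, not
imputed as zero.

## The synthetic study generator

Because labeled clinical recordings cannot ship with the package,
`simulateDataset()` generates statistically realistic mailed-device
assessments: a uniform 2–8 outbound delivery days, a truncated-Poisson
(mean 7) block of wear days, a uniform 2–8 return delivery days, and
mid-day activation/deactivation truncating the boundary days. Delivery
minutes jolt independently with probability 0.004 per minute, with
rounded-exponential magnitudes (mean 150 counts) placed on a random
nonempty subset of axes — transport shocks are short and heavy-tailed.
Wear-day waking minutes (07:00–22:00) are active with probability 0.55,
with Poisson counts under a raised-cosine diurnal intensity peaking at 800
counts/min mid-window; the squared magnitude of an active minute is split
across axes by Dirichlet(1,1,1) weights so per-axis and vector-magnitude
views stay consistent. Ten percent of wear days are non-adherent (active
probability scaled by 0.05). Nights are silent, dates are consecutive and
DST-free, and everything is reproducible from the config seed.

What this emulates well: class geometry (near-silent transit vs. diurnal
wear), participant grouping, truncated boundary days, non-adherence. What
it does not: device firmware quirks, genuinely ambiguous days (a device
riding in a courier van all day), seasonal and between-participant
heterogeneity of activity, or the count distributions of any particular
hardware. Synthetic performance therefore shows that the pipeline learns
the intended signal, not what its accuracy on clinical data would be. One
structural consequence of the defaults: a synthetic transit day totals on
the order of a thousand counts, so the 5000-count rule removes essentially
every delivery day, and the fully processed synthetic set is wear-only.
Supervised evaluation on synthetic data hence uses the minimally processed
set, while the full filters are validated by exact boundary fixtures and
subset/direction properties.

## Numerical choices and problem sizes

IRLS iterates to a 1e-10 tolerance with at most 100 iterations, guarding
weights below 1e-10 and probabilities at 1e-12; non-convergence raises a
classed error rather than returning a half-converged fit. Network
probabilities are clamped at 1e-12 for the loss. All randomness flows from
explicit seeds through one derivation function, so every stage — including
CSV outputs — is byte-reproducible.

The test suite and the acceptance script evaluate the pipeline on a
default synthetic study of 100 participants with two assessments each
(roughly 3400 days), five CV repetitions, and 10 training epochs for the
networks; gradient checks and algebraic oracles run on small shapes where
finite differences are exact. These sizes are the package's choices for a
convincing yet routine desk-scale experiment.

## Known limitations

* Day classification is binary; partial days that mix delivery and wear
  within one calendar date inherit a single label.
* The wear/non-wear literature's interval detectors are out of scope; the
  package classifies whole days only.
* The mixed model reverts to population predictions for unseen
  participants, which is exactly the cross-validation setting; its random
  intercept only helps when scoring additional days of known participants.
* Daylight-saving transitions are not modeled; timestamps are treated as a
  DST-free local clock.
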