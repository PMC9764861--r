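---
title: "Predicting brain age from resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting brain age from resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

EEG power spectra change systematically across the lifespan: band power
declines with age in all canonical bands, most strongly in delta. `eegage`
estimates a subject's chronological age directly from raw multichannel
resting-state EEG with a convolutional regressor, and ships everything
around that estimator: a synthetic cohort generator, session IO,
segmentation with artifact rejection, stochastic augmentation,
cross-subject cross-validation, session-level evaluation, age-group
boundary optimization, channel attribution, and a band-power/age screen.

The intended data shape is a clinical lifespan archive: 26-channel 10-10
recordings at 500 Hz, one eyes-open (EO) and one eyes-closed (EC) 2-minute
block per session, ages 5-88, with a per-sample artifact mask produced by
an upstream cleaning pipeline. The package consumes such masks; it does not
implement artifact detectors.

## The regression model

A segment of raw EEG `[C x L]` (by default 26 channels x 5 s at 500 Hz) is
expanded into a *stacked tensor* `[4 x C x L]`: four copies of the segment
with channel rows cyclically rolled by `0, 6, 12, 18` positions
(`j * floor(C/4)` for slice `j`). The first convolution sees every
electrode in several vertical neighborhoods, enlarging its effective
receptive field across the scalp; without stacking, a 7-row kernel reaches
only adjacent rows of the arbitrary channel ordering.

The network is four blocks of (2-D valid-padding convolution, batch
normalization, SiLU activation) with kernels `(7,64), (7,32), (7,16),
(7,8)` (electrode x time), common stride `(1,3)`, and widths 16, 32, 64,
128, followed by global average pooling and a linear head producing one
scalar, the predicted age in years. For the default configuration the
pre-pool feature map is `(128, 2, 25)`. At inference, predictions are
clamped at zero and the per-segment predictions of a session are averaged
into the session prediction; pooling all segments of both eye states is
equivalent to the segment-count-weighted mean of session means.

Two training losses are available at the segment level:

* **MAE** (absolute): `mean(|y - yhat|)`, in years.
* **MALE** (relative): `mean(|log(y+1) - log(yhat+1)|)`. A fixed age
  *ratio* costs the same everywhere on the lifespan, which shifts accuracy
  toward young subjects — the age range where a year matters most
  developmentally — at a small cost in the oldest group.

Optimization is Adam with reduce-on-plateau scheduling (factor 0.1,
patience 3 epochs, monitored on session-level validation MAE), early
stopping after 10 non-improving epochs, and the best-validation epoch's
parameters returned.

Because no deep-learning framework is part of the package's dependency
set, the network — convolution via im2col and BLAS matrix products, batch
normalization, SiLU, Adam, and full backpropagation including input
gradients — is implemented in base R. The backward pass is verified
against finite differences in the test suite.

### Initialization and numerical choices

* Weights: fan-in uniform `U(-1/sqrt(K), 1/sqrt(K))` under a recorded seed.
* The linear head's bias starts at the training-set mean age, so the
  optimizer only has to learn deviations from the cohort mean. With few
  optimizer steps this is the difference between converging and not; it is
  standard practice for regression heads.
* Batch normalization: biased variance for normalization, unbiased for the
  running statistics, momentum 0.1, epsilon 1e-5; evaluation mode uses
  running statistics, which makes evaluation deterministic.
* The non-negativity clamp applies at inference and metric time only; it is
  never inside the training gradient path.
* Training batches of size 1 are skipped (batch normalization is undefined
  there); the default batch size is 512 segments at full scale and 64 in
  the desk-scale test configuration.

## Cross-subject cross-validation

Subjects are shuffled under a seed and dealt round-robin into 10 folds; in
iteration `i`, fold `i` is the test set, fold `i %% 10 + 1` the validation
set, the rest train. All EO and EC segments of one subject share a fold, so
no information from a held-out subject ever reaches the optimizer. The
package also implements the deliberately wrong alternative — a segment
-level random split — solely to demonstrate the metric inflation it causes
(see below).

Fold metrics are aggregated with the upper 95% confidence bound
`mean + 1.96 * sd / sqrt(N_cv)` (sample standard deviation), the quantity
also used to select the optimal segment duration in the segment-length
sweep: longer segments give the network more context but lose more data to
artifact rejection, because a window containing any masked sample is
discarded.

## Augmentation

Five stochastic operators are applied to each training segment, each with
its own Bernoulli draw, in this order: additive Gaussian noise (std drawn
uniformly from [0, 1] uV per call, probability 0.5); zeroing of a run of
consecutive samples in each of k channels (k uniform on [1, 8] without
replacement, run length uniform on [1, 1800] samples per channel,
probability 0.7); per-channel amplitude scaling by a factor in [0.8, 1.2]
(probability 0.5); linear time-axis resampling by a factor in [0.8, 1.2]
with center-crop or edge-pad back to the original length (probability
0.5); and time reversal (probability 0.5). Augmentation is never applied
at validation, test, or prediction time.

Where the operator definitions leave room, the package fixes: operator
order is the listing order; the five draws are independent; dropout fills
with 0 uV and clips runs to stay inside the segment; the noise standard
deviation is shared across channels within a call, entries i.i.d.; time
warp restores length by center-cropping (stretch) or edge-padding with the
boundary value (shrink).

## The synthetic cohort generator

Real lifespan EEG archives are access-controlled, so the package ships a
generator whose cohorts have the same shape and carry a controllable age
signal. Each channel is a Gaussian process: a 1/f background (default RMS
2 uV) plus band-limited components in delta (1-4 Hz), theta (4-7), alpha
(8-12), and beta (12-30) whose RMS amplitudes scale log-linearly with age,
`a_b(age) = a_b0 * exp(s_b * (age - age_min))`. Negative per-year slopes
`s_b` (defaults: delta -0.015, theta -0.012, alpha -0.010, beta -0.006)
produce the monotone decline of band power with age that motivates the
whole enterprise; the slopes are chosen so that power roughly halves
between age 5 and 88 — the order of magnitude reported for lifespan EEG
cohorts. Ages are uniform on [5, 88]: archive summaries (mean 38.8, sd
19.1, range 5-88) are compatible with a roughly flat broad distribution,
and uniform keeps every decade testable. Alpha amplitude is multiplied by
1.8 in the eyes-closed block (the Berger effect), per-subject lognormal
amplitude variability (sigma 0.1) adds age-independent individual
differences, and an optional per-subject spectral *fingerprint* (a random
per-band log-amplitude tilt of standard deviation `fingerprint_strength`)
gives every subject a recognizable idiosyncrasy — the raw material of the
data-leakage demonstration. Transient artifacts (0.5-2 s, 10x channel RMS,
on 1-4 random channels) are injected at a configurable rate and marked in
the mask over their full extent.

A block is synthesized with a single inverse FFT from a complex Gaussian
spectrum shaped by the summed power spectra of its components — equivalent
in law to summing independently filtered noise, and several times faster.
Realized band power therefore fluctuates around its target like any finite
sample of a random process.

What the generator does *not* emulate: spatial covariance from volume
conduction, non-stationarity, alpha peak frequency shifts, line noise, or
realistic artifact morphologies. Tests passing on synthetic cohorts
demonstrate that the pipeline recovers a spectral age code under the
stated conditions — not that the architecture attains any particular
accuracy on clinical EEG.

## Desk-scale study conditions

The full-scale architecture is sized for GPU training. The test suite and
the acceptance script instead run a desk-scale configuration chosen once:
8 channels at 250 Hz, 12-s blocks, 2-s segments, the `tiny` architecture
preset (kernels `(3,16), (3,8), (2,8), (2,4)`, widths 8/16/32/64, stride
`(1,3)`), batch size 64, learning rate 3e-3, and at most 6-12 epochs.
The learning rate is an order of magnitude above the full-scale default
because a desk-scale run takes two orders of magnitude fewer optimizer
steps; the cohort slopes are steepened (delta -0.03 to beta -0.015) so the
age code is strong enough to be learned in those few epochs. With these
conditions a cross-validated model reaches a validation MAE less than half
that of the constant mean-age predictor within six epochs on one CPU.

## The data-leakage demonstration

With a segment-level random split, segments of one subject — overlapping
in time when the step is smaller than the segment — land on both sides of
the train/validation boundary. The demonstration trains the same
architecture twice on the same cohort (subjects with spectral
fingerprints, overlapping segmentation, no augmentation — augmentation
exists precisely to suppress memorization, and the demonstration measures
memorization) under the cross-subject and the random split, and compares
validation MAE at the *segment* level. Segment level matters: the
session-level pooling average rewards sessions that keep all
their segments, which the cross-subject split does and the random split
does not, and that bookkeeping artifact would otherwise mask the leakage
effect at desk scale. The random split's segment-level validation error
drops below the cross-subject one because near-duplicate windows and
subject fingerprints from training reappear in validation — an optimistic
number that would not survive genuinely new subjects.

## Age-group boundaries

Given true and predicted ages, `optimize_boundaries()` searches for the
partition of the age range into K groups that maximizes the balanced
accuracy (mean per-class recall) of the predicted group labels against the
true ones, under the constraint that the largest class is at most twice
the smallest (counted on true-age class sizes — boundaries partition the
true-age axis). Intervals are half-open with the last closed; the outer
boundaries are anchored at the data minimum and maximum. The optimizer is
a classic rand/1/bin differential evolution (population `15*(K-1)`, 200
generations, F = 0.8, CR = 0.9, seeded) with constraint handling by
rejection (`-Inf` objective): simple and exact, at the cost of wasted
evaluations near the constraint boundary. On integer-age data the
objective is piecewise constant, so the search is checked against an
exhaustive integer grid in the tests.

## Attribution

`integrated_gradients()` implements the path-integral attribution with a
midpoint Riemann sum (default 64 steps) from an all-zero baseline — no
signal, i.e. absent EEG, is the natural reference for a physical
amplitude measurement. The map satisfies the completeness axiom within
Riemann-sum error, is exact for an affine network (verified with the
identity-activation configuration), and is computed on the raw network
output before the non-negativity clamp. `smooth_grad()` averages maps over
noise-perturbed copies (default 16 samples, noise std 0.1 of the input
range). Channel importance sums absolute attribution over time and stack
axes after folding each stack slice back onto its source channel
(`(i + j*roll) mod C`), and distributions are summarized per stratum (eye
state, sex) by median and IQR using ECDF-based quantiles. The EO/EC
difference rule flags a channel when the absolute difference of stratum
medians exceeds twice the eyes-closed IQR (strict inequality, so a zero
IQR with any difference flags).

Per-segment scores (not per-session) enter the distributions: attribution
maps are computed at segment level, and aggregating before summarizing
would hide within-session variability.

## Band-power screen

`age_correlation_screen()` computes absolute band power per (channel,
band, eye state) with Welch's averaged periodogram (Hann windows of 2 s,
50% overlap, artifact-free windows only, units uV^2), correlates power
with age across sessions using Spearman's rank correlation (session-level
units: each session is one observation, matching how sessions are treated
as individual recordings), and applies Benjamini-Hochberg FDR correction
jointly across all cells of the screen. Cells with constant power are
reported as missing rather than given an arbitrary rank correlation.

## Known limitations

* The network trains on CPU via BLAS; full-scale (26-channel, 5-s,
  batch-512) training is possible but slow — the architecture is validated
  at full scale, trained at desk scale.
* The EDF reader/writer covers the plain 16-bit EDF subset used for
  session exchange (uniform sampling rate, no EDF+ annotations); the
  artifact mask travels as an extra 0/1 signal named `MASK`.
* The synthetic generator's stationary Gaussian model cannot probe
  robustness to non-stationarity or artifact morphology.
* `seglen_sweep()` retrains a model per candidate duration; at full scale
  this is a cluster job, and the package's tests exercise it on micro
  cohorts with one or two fold iterations.
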