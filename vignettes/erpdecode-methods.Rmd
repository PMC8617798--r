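---
title: "Segment-wise ERP decoding: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise ERP decoding: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpdecode)
```

This vignette explains the science and the engineering decisions behind
`erpdecode`: what the pipeline computes, which knobs matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open and a choice had to be made.

## The decoding model

The unit of analysis is a person's **target−standard difference
waveform**: the average ERP to rare target stimuli minus the average ERP
to frequent standards, a d×281 matrix (32 channels, −100…1000 ms at
256 Hz). Differencing cancels stimulus-nonspecific activity and
non-neural between-person offsets, which matters because the decoding
target — gender — is confounded with many such nuisance factors.

Decoding is hierarchical. The time axis is cut into 22 half-open 50-ms
bins anchored at −100 ms. Within bin *k*, each of the 12–13 timepoint
channel vectors is classified independently by a bottom-level classifier
trained on the corresponding vectors of all *other* persons, labeled by
their gender. The per-gender **vote rate** α(g) is the fraction of the
bin's vectors assigned to g; the bin's decision is argmax α, and the
per-person **rate** is α(true gender). The per-bin accuracy γ is the
mean rate over persons under leave-one-out cross-validation, and the bin
maximizing γ is adopted as the decision window. Reporting the *rate*
rather than the binary vote retains graded information (rates are
multiples of 1/13 for 13-sample bins) and is the statistic whose
per-person columns average exactly to the published per-segment
accuracies; the binary vote accuracy is reported alongside as a
secondary summary.

The bottom-level training set — all within-bin vectors of the training
persons — is the only construction consistent with leave-one-out over
persons and with a classifier that sees single timepoint vectors. No
feature scaling is applied: all features are amplitudes in microvolts on
a common reference, and scaling would distort the topographic amplitude
ratios that carry the signal.

## Preprocessing: parameters and numerical choices

* **Band-pass 0.01–30 Hz, half-amplitude, 24 dB/oct.** One second-order
  Butterworth section per band edge, applied forward and backward. The
  −3 dB point of a single pass *is* the half-amplitude (−6 dB) point of
  the zero-phase result, so the configured cutoffs need no pre-warping,
  and a second-order section doubled by the backward pass rolls off at
  asymptotically 24 dB/octave — both published characteristics follow
  from one realization. A cascade of two such zero-phase sections would
  instead give 48 dB/oct, which is why the package uses a single
  section. `filter_response()` evaluates the analytic magnitude so
  tests compare filtered sinusoids against closed-form gains rather
  than against the filter's own output. Each pass assumes zero initial
  conditions; startup transients decay inside the ~30 s of stimulus-free
  padding that recordings carry at both ends.
* **Blink correction.** Principal components are computed over channels;
  the component whose time course correlates most strongly (absolute
  value) with the mean of Fp1/Fp2 is removed (1 component by default).
  Removing a centered component redistributes the blink's *mean* into a
  small DC offset per channel; this is harmless because baseline
  correction later removes any constant. ICA is a common alternative but
  is deliberately out of scope: the PCA criterion is simple, fast, and
  testable with a known mixing model.
* **Epoch grid.** −100 ms is not an integer number of samples at 256 Hz
  (25.6 samples). The grid takes every sample index i with
  −100 ≤ i·Δ < 1000 (Δ = 1000/256 ms), i.e. i = −25…255, reproducing the
  281 timepoints of the original acquisition. The baseline is the 25
  pre-stimulus samples (i = −25…−1); the onset sample is excluded so
  stimulus-driven activity never leaks into the baseline estimate.
* **Artifact rejection** is per epoch, placed *before* baseline
  correction (an epoch sitting on a large offset must be rejected on its
  recorded amplitude, not after the offset is subtracted), with a strict
  threshold: amplitudes must exceed ±75 μV to reject, so an epoch
  peaking exactly at 75 μV is kept. Whether rejection should run on
  continuous data instead is ambiguous in standard practice; per-epoch
  was chosen because the workflow places detection after epoching, and
  it makes the kept-trial counts exactly interpretable.
* **Detrending** is a per-channel, per-epoch least-squares line over the
  full window, removed after baseline subtraction. Removing the fitted
  intercept shifts the baseline mean when the epoch contains a large
  one-sided deflection (the fitted line absorbs part of the component's
  mass); peak-minus-baseline amplitudes are invariant to this shift,
  which is why component amplitudes survive the step unchanged.
* **Segment membership** uses half-open intervals `[start, end)` with
  assignment by exact sample latency. This yields 17 bins of 13 samples
  and 5 of 12 (summing to 281), with 13 samples in the two
  neurophysiologically interesting bins (300–350 and 650–700 ms) —
  consistent with published per-person rates being multiples of 1/13.
  kmax is derived from the grid span, never hard-coded.

## Classifiers

The four bottom-level families are the ones routinely compared in EEG
decoding, each behind one configuration object: 3-NN with Euclidean
metric; Gaussian naive Bayes; a 100-tree random forest with
√d-sized feature subsets (the implementation uses the Gini impurity
criterion of the underlying forest library; gain-ratio splitting, a
C4.5 notion, is not available in R forest implementations and the
difference is immaterial for axis-aligned splits on 32 continuous
features); and a polynomial-kernel SVM (degree 3, cost 1, no scaling).
Stochastic fits are explicitly seeded per cross-validation fold.
Vote ties — possible only in 12-sample bins — break toward the
training-set majority gender and emit a message.

## The synthetic cohort generator

The generator's defaults are the acquisition conditions of the study
this package re-implements: 20 persons (10 female/10 male), 32 channels,
256 Hz, 300 stimuli (20% targets), 150 ms stimulus duration, 1000 ms
inter-stimulus interval, ~30 s padding at both ends. Evoked responses
are sums of Gaussian bumps (N1 110 ms occipital, P2 190 ms and N2 250 ms
fronto-central, P3 420 ms parietal with 120 ms width); standards carry a
4× attenuated P3. Gender effects are boxcar amplitude offsets on the
parietal target response: +2 μV for men at 300–350 ms and +2 μV for
women at 650–700 ms — the direction of the reported difference.
Background activity is 1/f noise (σ = 9 μV), slow sinusoidal drift,
Poisson-timed stereotyped frontal blinks (~10/min, ~110 μV), and
per-trial artifact bursts (~120–170 μV, probability 1/3) that drive
trial dropout: after ±75 μV rejection, roughly 40 of 60 target and 160
of 240 standard epochs survive, matching the reported kept-trial counts.
Per-person individual differences are lognormal amplitude jitter
(σ = 0.15) and Gaussian latency jitter (σ = 10 ms) on every component.

What the generator does **not** emulate: volume conduction from dipolar
sources (topographies are fixed weight profiles), non-stationary alpha
rhythms, heteroscedastic noise across channels, eye movements other than
blinks, and any person-level covariates beyond gender. Passing tests on
synthetic cohorts therefore demonstrates that the pipeline recovers the
structure the generator encodes — windowed topographic amplitude
differences under realistic noise — not that real recordings contain
such structure.

`simulate_erp_cohort()` is a documented shortcut that emulates the
*output* of preprocessing (template difference + band-limited residual
noise at the level expected after averaging ~40/160 trials). Calibration
studies of the classification stack (null distributions, effect-size
sweeps) use it because the continuous stage is not what they probe;
experiments that validate the pipeline itself (parameter recovery,
determinism, dropout calibration) always run the full raw-EEG path.

## Validation experiments and their sizes

* **Aggregation oracles.** Vote, rate, and accuracy are checked against
  brute-force counting on every binary label sequence up to length 10
  (exhaustive, 2046 sequences).
* **Published-table consistency.** The per-person rate tables of the
  reference study (bundled as plain text) must reproduce its per-segment
  summary cells through the mean-and-round statistic, its proportions of
  above-chance persons, its above-chance segment counts in 100–800 ms,
  and its signed-rank statistic (V = 187 on the naive-Bayes segment-9
  column; the package reproduces it exactly with one-sided ranks on the
  printed two-decimal rates, m = 8 Bonferroni).
* **Parameter recovery.** 20 replicate cohorts are simulated through
  the full raw-EEG pipeline with the late (650–700 ms) effect as the
  *only* gender difference; the naive-Bayes γ column must select
  segment 16 in the majority of replicates. Twenty cohorts keep the
  experiment near ten minutes on a single CPU while making the majority
  criterion meaningful.
* **Permutation null.** 50 cohorts with genders randomly reassigned.
  The mean γ sits *slightly below* 0.5 (≈0.45–0.47 across classifiers
  and segments): with 20 persons, excluding the test person leaves their
  (permuted) class with 9 of 19 training persons, and every classifier
  family tilts toward the better-represented opposite class — a class
  prior for naive Bayes, neighbour availability for k-NN. This
  pessimistic bias of leave-one-out decoding under the null is a known
  small-sample phenomenon, intrinsic to the protocol rather than to this
  implementation; it is visible even on the signal-free pre-stimulus
  segment. The test suite therefore asserts that the null mean lies in a
  band around-and-below chance and far beneath the effect-condition
  accuracy, rather than asserting unbiasedness.
* **Kept-trial calibration** checks that simulated dropout lands inside
  the reported 40 ± 8 / 160 ± 32 ranges.

## Known limitations

With 20 persons, γ has a granularity of 1/260 and leave-one-out
estimates are high-variance; segment selection by argmax is accordingly
optimistic, and the package reports the full γ table plus per-person
rates so readers can judge stability. The Wilcoxon p-values inherit the
discreteness of tied, rounded rates (average ranks, normal
approximation), and the Bonferroni family size defaults to 8 — the four
classifiers times the two examined segments — because the original
correction's family is not otherwise determinable. EDF support covers
the common 16-bit continuous-recording case only (one sampling rate,
whole-second records).
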