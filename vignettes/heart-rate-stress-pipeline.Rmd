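---
title: "From wearable heart-rate streams to daily stress labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable heart-rate streams to daily stress labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrstress)
```

`hrstress` asks whether the shape of a whole day of heart-rate readings,
collected passively by a wrist wearable in free-living conditions, carries
enough signal to classify that day as stressful or not. This vignette is
the package's own account of the model, its assumptions, the tunable
parameters, and the places where the design was genuinely open.

## The data problem

Wearables do not sample heart rate on a clock. They read more often while
the heart rate is moving (exercise, arousal) and less often when it is
stable (sleep), they are taken off for hours at a time, and the daily
self-report ("Was today stressful?") is frequently forgotten. The unit of
analysis is therefore the *participant-day*, and three defects have to be
handled before any modelling: days with readings but no label, days with
labels but no readings, and days whose readings cover only part of the
day.

The filtering rule is deliberately blunt: a day enters the analysis only
if it has a label **and** readings in more than 21 of the 24 clock hours,
where an hour counts as covered if at least one reading falls inside it.
The threshold is exposed (`min_hours_exclusive`, default 21, strict
inequality) because the boundary is genuinely ambiguous in this
literature — cohorts are often described as averaging "around 21 hours" of
coverage while the stated rule is "more than 21 of 24"; we implement the
literal strict reading and let the analyst lower it.

## Regularization: maximum, carry, downsample

Valid days are regularized in three steps (`minute_resample()`,
`fill_missing()`, `downsample()`):

1. **Per-minute maximum.** All readings in one minute collapse to their
   maximum. Averaging would smear exactly the transient surges that are
   informative here; duplicated exercise-mode readings are absorbed by
   the same rule.
2. **Carry-forward / carry-backward.** Empty minutes take the last
   observed value (the device stays silent when the rate is stable, so
   stability is the right prior); minutes before the first reading take
   the first observed value, which typically covers sleep. A provenance
   mask records which rule produced each slot.
3. **Window-maximum downsampling** to 3-minute windows aligned at
   minute 0, giving the 480-point day vector. The within-window reducer
   is configurable (`reducer`); the maximum is the default for
   consistency with step 1, and on the canonical 10-minute example
   fragment `[58, ?, 67, ?, ?, ?, ?, 61, 62, ?]` it reproduces both
   published path outputs: fill-then-downsample gives `67, 67, …`,
   while direct 3-minute resampling of the raw readings gives `67, 62`.
   The disagreement is the point: the direct path forgets carried values
   and is provided (`direct_resample()`) only as the comparison oracle.

Order of stages matters: interpolating at 1 minute first and downsampling
second preserves elevated readings longer; `hrstress` treats the
two-stage path as the pipeline and keeps the direct path for tests.

## Feature modalities

Each 480-point day vector `hr_0..hr_479` feeds five modalities:

- **org** — the vector itself (480 features).
- **fft** — magnitudes of the discrete Fourier transform
  \(HR_k = \sum_n hr_n e^{-i 2\pi k n / N}\), keeping
  \(k = 0..239\). A real signal's spectrum is conjugate-symmetric, so
  the upper half is redundant; 241 bins are non-redundant
  (DC through Nyquist) and the Nyquist bin is dropped to match the
  240-wide contract with minimal information loss. A direct
  \(O(N^2)\) evaluation (`dft_oracle()`, with `idft()` for the inverse)
  exists purely as the independent reference the fast path is tested
  against.
- **wave50 / wave150 / wave250** — modulus of a continuous wavelet
  transform with the complex Morlet kernel
  \(\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}\) on integer scales
  \(1..J\), \(J = 10, 30, 50\). Although such scale grids are sometimes
  described with DWT vocabulary, the Morlet wavelet is non-orthogonal
  and admits no literal discrete wavelet transform; a CWT on an integer
  scale grid is the construction that actually produces \(J \times 480\)
  coefficient matrices. The modulus is taken because PCA needs
  real-valued inputs (raw real parts and power are available via
  `value =`). \(\omega_0\) defaults to 5.0, the common Morlet choice
  (the trade-off between time and frequency localization); it is
  configurable because nothing in the problem pins it down.

Two numerical details of the CWT deserve mention. The kernel is truncated
at \(|t| \le 5\) standard deviations of its Gaussian envelope, where it
has decayed below \(4 \times 10^{-6}\); and the day's mean is removed
before convolving. The DC level of a day belongs to the `org` and `fft`
modalities; inside the CWT it would only leak through the imperfect
zero-mean of the integer-sampled kernel (noticeable at scale 1, where
\(\omega_0 = 5\) rad/sample is beyond Nyquist) and through the
zero-padded boundaries. With the mean removed, a constant day has exactly
zero coefficients at every scale and position. Boundary handling is
zero-padding; coefficients within \(5j\) samples of an edge sit inside
the usual cone of influence and are attenuated accordingly.

The wavelet matrices are compressed by a **per-day PCA**
(`perday_pca()`): the \(J\) scale rows of one day are the observations,
the 480 positions the variables, and each row is projected onto the
leading 5 components, giving \(5J\) features per day. The orientation is
forced by the target shapes (\(J \times 5\)); centering is per day. On
simulated days the 5 components retain a median of well over 95% of the
per-day variance (asserted in the test suite). Because the PCA sees one
day at a time, feature extraction cannot leak information across days —
permuting days permutes feature rows identically, which is also tested.

## Classification and evaluation

Six classifier families (`six_classifiers()`) are crossed with four
imbalance/dimensionality settings (`four_settings()`): balanced class
weights (BCW) or SMOTE, each with or without PCA, evaluated by
stratified ten-fold cross-validation repeated ten times
(`cv_config()`, 100 held-out evaluations per configuration).

Defaults, all configurable, where the analysis protocol is silent:

- Logistic regression is ridge-penalized (`glmnet`, \(\lambda = 1/n\),
  the weakly-informative analogue of the common unit-cost convention);
  with 240–480 features and under 200 days an unpenalized fit is
  degenerate.
- SVMs use cost 1 and kernel width \(\gamma = 1/p\) on standardized
  features. The polynomial kernel is degree 3 and *inhomogeneous*
  (`coef0 = 1`): with `coef0 = 0` and \(\gamma = 1/p\) the cubic kernel
  is numerically near-diagonal (\((u \cdot v / p)^3\)), the machine
  memorizes its support vectors and generalizes at chance.
- Both ensembles use 100 trees; gradient boosting uses depth 3 and
  learning rate 0.1.
- Features are standardized with training-fold mean/sd before logistic
  regression, SVMs and PCA; tree ensembles see raw features unless PCA
  is in play.
- SMOTE (5 minority neighbours, uniform interpolation weights) and PCA
  (components retained up to 95% cumulative variance) are fitted
  **inside each training fold only**. Fitting SMOTE before splitting is
  a well-known leakage artifact: synthetic minority points interpolate
  across what later becomes the test fold. The test suite audits this by
  shuffling held-out labels and asserting the fitted preprocessing state
  is bit-identical. In the SMOTE+PCA setting, SMOTE runs first and PCA
  is fitted on the resampled training data.

Reported metrics per configuration: training accuracy, test accuracy,
and balanced test accuracy (mean of per-class recalls), each as
mean ± sd over the 100 fold evaluations. `run_grid()` covers the full
5 × 4 × 6 grid and flags the best setting per (modality, classifier);
`best_configuration()` picks the per-modality winner by mean test
accuracy, breaking ties by balanced accuracy and then grid order.
`transfer_evaluate()` refits the winning configuration on one
participant and evaluates on another, reporting the confusion matrix
with the non-stressful class first.

## Statistical comparison

`build_report()` assembles the comparison framework over a completed
grid: the majority baseline (the larger class fraction, in percent); a
Kruskal–Wallis omnibus test across the five modalities' best-fold
accuracy distributions (rank-based, tie-corrected — CV accuracies on a
fixed cohort are heavily tied); Dunn's pairwise z-tests on the joint
ranking with Bonferroni correction (\(p_{adj} = \min(1, 10\,p)\) for the
10 pairs), computed downstream of the omnibus test; and per-modality
two-sided one-sample t-tests against the baseline (two-sided because a
modality can also sit *below* the baseline). Significance is 0.05
throughout, configurable. Calibration of both tests (type-I error at the
nominal level, uniform null p-values) is asserted by Monte-Carlo in the
test suite.

One caution the package enforces only by documentation: fold accuracies
from repeated cross-validation are positively correlated (every fold
shares training data with every other), so the naive
\(sd/\sqrt{100}\) standard error understates the real sampling
variability. Where the test suite brackets chance-level behaviour it uses
the corrected resampled standard error
\(sd \cdot \sqrt{1/n + n_{test}/n_{train}}\) (Nadeau–Bengio), and t-tests
between configurations on the same folds should be read with the same
caveat.

## The synthetic cohort generator

Real cohorts of this kind are confidential, so `sim_config()` /
`simulate_cohort()` generate streams with the structure the pipeline
assumes, and the whole analysis is exercised end to end on them.

The latent heart rate of a day is a continuous-time process evaluated at
1-second resolution: a circadian baseline (wake mean 75 bpm, sleep mean
55 bpm between 23:00 and 07:00, smoothed with a 31-minute moving
average, with 3 bpm between-day jitter of the wake level), plus
exponentially decaying activity bursts (Poisson count, default 4/day;
peak 20–60 bpm; nominal length 5–40 min with decay constant length/3),
plus — on stressful days only — a baseline shift (default 3 bpm), a
slow sinusoid with period drawn from 2–4 h (default amplitude 6 bpm,
emulating the elevated low-frequency spectral amplitude that
distinguishes stress days), and a burst-rate multiplier (default 1.8,
interpreted as more arousal episodes rather than taller ones).
Observations add Gaussian noise (sd 2 bpm) and clip to [30, 220] bpm.

Sampling is adaptive with a single threshold, mimicking the described
device behaviour: while the latent rate exceeds the wake baseline by
15 bpm, inter-reading gaps are drawn from 10–60 s; otherwise from
3–8 min. Whole clock hours are dropped independently with probability
0.05 (device off wrist — the failure mode that makes days miss the
coverage rule), and each day's label is withheld with probability 0.1
(forgotten self-report). The LF-oscillation parameters are drawn every
day regardless of the stress flag so that runs from the same seed with
the flag toggled stay stream-aligned; with bursts and oscillation
disabled, toggling the flag changes the latent signal by exactly the
baseline shift, which is how the tests isolate each effect.

Defaults were chosen once as plausible free-living values — per-day
reading counts (a few hundred at rest, more during bursts), sleep
bradycardia depth, burst sizes — since published summaries of such
cohorts report wide per-participant variation without usable
distributions; they are stand-ins, not calibrated estimates.

What the generator does **not** emulate: beat-to-beat (RR-interval)
structure and HRV, accelerometry, weekday/weekend structure, multi-day
dependence of stress states, or sensor artifacts such as motion-induced
spikes. Passing tests therefore show that the pipeline recovers a
low-frequency + variability stress signature planted in otherwise clean
circadian data — they do not show that real stress manifests this way,
which is exactly the question a real cohort must answer.

## Study-scale behaviour and problem sizes

The package's own end-to-end checks run on a 200-day single-participant
cohort (about 160 valid days after coverage filtering and label dropout,
stress prevalence 0.3) — comparable to the ~185-day cohorts this kind of
study analyzes. With a strong planted effect (LF amplitude 8 bpm, burst
multiplier 1.8), the FFT modality under BCW with the polynomial-kernel
SVM reaches a mean balanced test accuracy above 0.70 across 10×10
stratified CV; with all stress effects zeroed the same configuration is
statistically indistinguishable from 0.5 under the corrected resampled
standard error. Unit tests use far smaller fixtures (tens of days,
3–5 folds) to keep the suite fast; statistical calibration uses 1000
null replicates.

## Known limitations

- The day boundary is local midnight in a single configured time zone
  per cohort; readings carry no zone information in the CSV dialect, so
  cross-time-zone travel is not represented.
- Carry-forward filling can bridge arbitrarily long interior gaps on
  days that still pass the coverage rule; the provenance mask makes such
  stretches identifiable but the pipeline does not down-weight them.
- `best_configuration()` selects on the same folds the statistical
  report then reuses; with 24 configurations per modality there is a
  winner's-curse optimism in the per-modality best distribution, as
  there is in any protocol of this shape.
- The generator's stress effect is global to the day; it cannot express
  stress confined to part of a day, which the wavelet modalities would
  be best placed to detect.
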