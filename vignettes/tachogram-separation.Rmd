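---
title: "Separating respiratory influences from the tachogram: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating respiratory influences from the tachogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tachosep)
```

## The problem

Heart-rate variability (HRV) is read as a window on autonomic nervous
system activity, but a large share of short-term HRV is driven directly by
breathing — respiratory sinus arrhythmia (RSA), the vagally mediated
heart-rate oscillation at the breathing frequency. When the breathing rate
drifts, or drops toward the low-frequency band, spectral HRV indices
confound respiratory mechanics with autonomic state. One remedy is to
record respiration alongside the ECG and split the tachogram (the series of
RR intervals, resampled onto a uniform 4 Hz grid) into two parts:

t(n) = t_r(n) + t_resid(n),

a respiration-driven component t_r and a residual t_resid holding every
heart-rate variation unrelated to breathing. This package implements five
data-driven estimators of t_r that have been proposed for this task, a
common evaluation toolkit (time-domain NRMSE plus Welch LF/HF band-power
errors), two benchmark protocols that compare the estimators, and a
ground-truth synthetic generator so the whole chain is testable without
human recordings. In every method the residual is obtained by subtraction,
so the decomposition identity above holds to machine precision by
construction; `conservation_error()` verifies it.

## Preprocessing

`build_tachogram()` interpolates the RR value at each beat instant with a
natural cubic spline and samples it at 4 Hz over the beat span (no
extrapolation). RR intervals outside a 200–3000 ms guard range are flagged
with a warning and a mask, never silently dropped or corrected: ectopic
handling is left to the analyst. `highpass_respiration()` removes baseline
wander below 0.05 Hz. The filter family and order are not fixed by the
method definitions, only the cutoff; we use a 4th-order Butterworth applied
forward and backward (`signal::filtfilt`). Zero phase matters here: a
causal filter's group delay would shift respiration relative to the
tachogram and corrupt the delay structure the FIR/OSP models estimate.

## The five separators

**LMS adaptive filtering** (`separate_lms`). Respiration feeds an FIR
filter of M taps whose output is the RSA estimate; the weights follow the
stochastic-gradient rule w(n+1) = w(n) + 2 mu e(n) x(n) that minimizes the
mean-squared error e between tachogram and estimate. Both inputs are first
smoothed with a Savitzky–Golay filter (order 1, 5-sample windows); the
smoothing is an integral part of the method — without it performance drops
sharply. Two passes are run: the first from zero weights over the whole
record, the second restarting from the converged weights, which removes the
zero-initialization transient. Defaults are M = 126 at 4 Hz (a published
2 Hz design scaled by two) and mu = 0.1 times the stability bound
`lms_stability_bound()`, the classical power-normalized bound
1 / ((M + 1) P_r). The filter adapts on the demeaned tachogram: the ~900 ms
mean RR is not respiration-driven, and if left in place the constant error
term dominates the weight updates and the filter never converges (the mean
returns to the residual through the subtraction step).

**Two-channel ICA** (`separate_ica`). Respiration and tachogram are treated
as a 2-sensor linear mixture of two independent sources, unmixed by
FastICA (`ica::icafast`, seeded for reproducibility, up to five restarts).
The source best correlated with respiration is labeled respiratory; since
ICA sources are scale-ambiguous, the tachogram is regressed on the
normalized sources (with an intercept absorbing the mean RR) to restore ms
units. The method's core assumption — statistical independence of
respiration and the residual heart-rate dynamics — is physiologically
doubtful, and the benchmarks reflect that; it is included as a published
comparator.

**FIR system identification** (`separate_armax`). The tachogram is
modeled as a linear combination of the current and previous p respiration
samples; p = 12 (3 s at 4 Hz) by default, long enough for all delayed
respiratory effects. Coefficients come from a QR least-squares fit on the
fully populated regressor rows. The fit carries an intercept that absorbs
the mean RR but is excluded from t_r: without it, the interaction of the
large tachogram mean with the regressors' small sample means leaks into the
FIR coefficients (verified to destroy exact kernel recovery), and the mean
heart rate is not a respiratory quantity. The first p output samples use
zero-padded regressors and are flagged in the diagnostics; benchmark
metrics exclude them.

**Multiscale PCA** (`separate_mspca`). Both signals are decomposed with a
Daubechies-4 wavelet to level 5 — at 4 Hz the approximation then holds
frequencies below 0.0625 Hz, where no cardiorespiratory interaction is
assumed. At each detail scale, PCA on the centered two-column coefficient
matrix asks whether one direction explains more than 90% of the variance;
if so the channels are strongly linearly related at that scale and the
tachogram coefficients are replaced by their rank-1 reconstruction along
the first eigenvector (this keeps ms units; only the tachogram channel is
reconstructed), otherwise the scale is zeroed. t_r is rebuilt from the
modified detail coefficients with the approximation set to zero.

**Orthogonal subspace projection** (`separate_osp`). A respiratory
subspace basis X collects the five wavelet detail signals of respiration,
each at delays 0–11 samples, plus an all-ones column estimating the bias:
5 × 12 + 1 = 61 columns. t_r = X (X'X)^-1 X' t, computed by QR rather than
an explicit inverse. OSP combines the multiscale view of MSPCA with the
delay modeling of the FIR method. Note that the intercept assigns the mean
RR to t_r — a convention difference from the other methods discussed under
"Scoring" below.

## Numerical choices

*Wavelet transform.* No decimated transform is used: the per-scale PCA and
the delayed-detail basis both need full-length, sample-aligned detail
signals whose sum with the approximation reconstructs the input exactly.
The package therefore implements the maximal-overlap discrete wavelet
transform (MODWT, Percival–Walden pyramid) with db4 filters and circular
boundary treatment; additivity then holds to ~1e-12 and the transform
preserves energy. Circular wrapping introduces edge artifacts within about
one filter width of the record ends, which is acceptable for 6-minute
records and is the price of exact additivity.

*OSP conditioning and prefix.* The delayed detail columns are strongly
collinear (condition numbers around 1e8 on typical records). The projection
is fit only on rows where every delayed column contains past samples
(samples 12..N). For the flagged leading samples the columns wrap
circularly — zero-padding them instead makes the prefix predictions explode
(~1e6 ms), because the large canceling coefficients of a collinear basis no
longer cancel. If the condition number exceeds 1e10 a small ridge
(1e-8 tr(X'X)/61) is added and recorded in the diagnostics.

*LMS stability.* The exact constant in the step-size bound is a design
choice; we use mu_max = 1 / ((M + 1) P_r), which halves under doubled
reference power and approximately halves under doubled filter length.

*Welch settings.* Eight sections with 50% overlap (segment length
floor(2N/9)), periodic Hamming window, per-segment mean removal,
1024-point FFT, one-sided density scaled so its integral approximates the
variance. Records too short for eight 16-sample sections fall back to
fewer sections with a warning. Band powers are trapezoidal integrals over
[lo, hi); the total-power band defaults to 0.04–0.40 Hz, the LF+HF span,
as no wider convention is fixed for short records.

*Scoring and the unidentifiable mean.* The constant mean RR cannot be
attributed to either component by any data-driven criterion, and the
methods disagree by convention: OSP's intercept puts it in t_r, the other
four leave it in the residual. Ground-truth recovery on synthetic cohorts
is therefore scored with NRMSE after removing each signal's mean (and
skipping the flagged 12-sample prefix). Inside the benchmark studies the
raw NRMSE is kept, because there the ground truths and estimates are
produced by the algorithms themselves — including their bias conventions —
and the windowed stability study's known OSP weakness (segment-to-segment
bias jumps) only appears in raw scores.

## The synthetic generator

`generate_subject()` emulates a 6-minute seated baseline recording at 4 Hz:

* respiration: a narrowband oscillation whose instantaneous frequency
  drifts slowly inside 0.2–0.3 Hz, with mild (±20%) amplitude modulation,
  high-pass filtered at 0.05 Hz;
* RSA component: a causal FIR kernel (default 5 taps, unit absolute sum)
  applied to respiration, scaled to 40 ms — a typical resting RSA
  amplitude; linearity and the short delay are exactly the model class the
  FIR/OSP methods assume;
* residual: a 0.1 Hz oscillation of 30 ms (the Mayer-wave/baroreflex rhythm
  of the LF band) plus AR(1) noise (pole 0.9, 10 ms) for 1/f-like
  background, generated from a random stream independent of respiration so
  ground-truth separability is well defined;
* tachogram: 900 ms mean RR plus both components.

Per-subject seeds derive deterministically from the cohort seed, so a
cohort regenerates bit-identically. An IPFM beat generator (`ipfm_beats`)
can turn the continuous tachogram into RR intervals to exercise the
resampling front end.

What the generator does *not* emulate: nonlinear and nonstationary
cardiorespiratory coupling, ectopic beats and measurement artifacts,
baroreflex feedback between the residual and respiration, and breathing
that wanders outside the HF band. Because the RSA truth is linear-FIR by
construction, the generator favors the linear-regression methods in exactly
the way their own model class predicts; passing recovery tests here shows
correctness of the implementations, not superiority on arbitrary real
data. The study protocols themselves (splicing components across subjects,
cross-validating over algorithms) are the device that avoids baking one
method's assumptions into the ground truth.

## Benchmark protocols

The **simulation study** (`run_simulation_study`) builds realistic ground
truth by splicing: algorithm a extracts the reference subject's t_r and
each test subject's t_resid; their sum is a composite tachogram whose two
components are known; every *other* algorithm b then separates the
composite given the reference respiration, and is scored against the known
parts. Excluding b = a cross-validates over algorithms. With one reference,
35 test subjects and five algorithms this yields 35 × 5 × 4 rows of six
metrics. A separator whose output depends only on respiration (the exported
`oracle_gain_separator`) recovers both components without error and anchors
the harness at zero.

The **stability study** (`run_stability_study`) compares each algorithm's
full-window (360 s) separation against the concatenation of its three
120 s-window separations of the same record — a pure robustness probe:
window-independent methods score zero.

`summarize_study()` reduces either result to per-algorithm medians,
quartiles and 1.5-IQR ranges, the tabular counterpart of boxplots.

## Problem sizes and defaults used in the shipped checks

The packaged tests run the full chain on cohorts of 20 synthetic subjects
(360 s at 4 Hz, fixed seed) for conservation and ground-truth recovery,
and validate the benchmark combinatorics on a 36-subject cohort of 120 s
records (the row count depends only on the cohort and algorithm counts,
not the record length). On the default cohort, the delay-based methods
(OSP, FIR) reach median demeaned NRMSE of the respiratory component well
below 0.2 and beat the ICA separator's residual recovery — the qualitative
ranking the benchmark protocols are designed to expose.

## Limitations

All five separators are linear; nonlinear coupling, blood-pressure
pathways, and paced-breathing broadband normalization of the FIR model are
out of scope, as are R-peak detection and ectopic correction upstream of
the RR series. The MODWT's circular boundary and the Welch segmentation
both assume the record is at least a few breathing cycles long; records
shorter than 2^5 samples cannot be decomposed to level 5 at all. ICA's
independence assumption makes its separation unreliable here — a finding
the benchmarks are designed to make visible, not a defect of the
implementation.
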