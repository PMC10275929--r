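---
title: "Window-based affective state estimation from physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based affective state estimation from physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioaffect)
```

## The problem

Affective states can be placed on Russell's circumplex: a valence axis
(pleasant--unpleasant) and an arousal axis (activated--calm). Because the
autonomic nervous system modulates skin conductance, cardiac dynamics and
respiration involuntarily, these signals carry information about where on
that plane a person currently sits. `physioaffect` implements a complete
window-based estimation pipeline for three wearable channels — skin
conductance (GSR, µS at 51.2 Hz), electrocardiogram (mV at 250 Hz) and
respiration rate (breaths/min at 25 Hz) — together with a seeded synthetic
cohort generator that emulates a picture-viewing stimulation protocol, so
that every stage of the pipeline can be exercised and tested without any
human recordings.

## Labels on the valence--arousal plane

Stimulus ratings arrive on the 1--9 scale used by normed picture databases
and by the pictorial self-assessment scale; `rescale_rating()` centres
them to $[-4, 4]$ so the origin is affective neutrality.
`assign_quadrant()` partitions the plane into the four Russell quadrants
(HAHV, HALV, LALV, LAHV) plus a closed central neutral box of half-width 1
on both axes — 6.25% of the plane. Four classification problems are built
from the quadrants: high/low valence and high/low arousal (binary, neutral
images excluded), the four-quadrant problem, and the five-class problem
that adds the neutral class.

Self-reports are compared with the database ratings by
`consistency_filter()`. We exclude an image only when the self-assessed
quadrant is the *diagonal opposite* of the database quadrant (both axis
signs flipped, neither point neutral): that is the unambiguous reading of
"completely inconsistent", and single-axis disagreements — which are
common and informative — are retained. The alternative (exclude on any
quadrant mismatch) was considered and rejected because it removes a large
fraction of near-boundary images.

## Preprocessing

All filtering is zero-phase Butterworth (`signal::filtfilt`), order 4.
The order is a design choice (the analysis chain needs *some* order and
electrodermal practice favours low-order zero-phase filters); zero-phase
matters because phase lag would smear features across the 0.5-s window
boundaries. The raw conductance is denoised at 5 Hz, then split into the
tonic level (SCL, low-pass 0.1 Hz) and the phasic response (SCR, high-pass
0.1 Hz). The split is a complementary filter pair, so SCL + SCR
reconstructs the denoised signal only approximately; the package treats a
residual power ratio below 5% on band-limited inputs as conformant, and
tests assert it.

R peaks are detected on the native 250 Hz ECG *before* any resampling
(band-pass 5--15 Hz, squared energy, 150 ms smoothing, adaptive threshold,
250 ms refractory period, refinement to the raw-ECG local maximum).
Inter-beat intervals outside (200, 3000) ms are discarded as
implausible. The instantaneous heart rate, 60000/IBI in bpm, is assigned
at the second beat of each interval and held piecewise constant.

The SCL, SCR and respiration streams are then linearly interpolated onto
a shared 36.5 Hz grid (`synchronize()`); linear interpolation is exact
for affine signals and adequate for these level-type streams. Whether
filtering should happen before or after synchronization is genuinely
open; this package filters at native rates first, which preserves the
full ECG bandwidth for beat detection.

Baseline normalization subtracts each level stream's scalar mean over the
4-minute rest interval from the SCL, heart-rate and respiration streams.
The phasic SCR is zero-mean by construction and the raw ECG waveform is
not a level signal, so neither is shifted.

## The 23 window features

Features are computed on non-overlapping 0.5-s windows tiled from each
image onset (blank slides, self-assessment gaps and the rest baseline are
excluded from classification data). Fifteen are electrodermal: mean,
population standard deviation, min, max and max−min of SCL and of SCR;
mean first and second SCL derivatives (µS/s, µS/s²); and the number,
mean amplitude and amplitude standard deviation of SCR peaks. A peak is a
local maximum whose rise from the preceding minimum strictly exceeds
0.03 µS, the midpoint of the conventional 0.01--0.05 µS detection range;
`PA_mean`/`PA_std` default to 0 when no peak falls in a window so that
classifiers always receive complete vectors. Seven are cardiac: the five
HR statistics plus running SDNN and RMSSD. One is the mean respiration
rate.

A 0.5-s window cannot contain two heartbeats, so per-window SDNN/RMSSD
would be undefined. The package therefore maintains a rolling buffer of
the intervals from the trailing 15 s — one image presentation — and emits
its SDNN/RMSSD each window (`sDNN_mean`, `rMSSD_mean`). The buffer length
is a design choice: long enough for ~15--20 intervals, short enough to
track within-session changes, and consistent with excluding
frequency-domain HRV, which needs minutes of data. All standard
deviations in the package are population (divide by *n*) for internal
consistency; the choice is immaterial to classification after z-scoring.

## ReliefF and the optimal feature set

`relieff()` estimates each feature's relevance for one participant: for
every training window, the k nearest same-class windows (hits) and the k
nearest windows of each other class (misses) are found under Manhattan
distance on range-normalized features, and the weight of a feature is the
prior-weighted mean miss difference minus the mean hit difference. All
instances are evaluated (m = all), which removes sampling noise and makes
the weights order-invariant; ties break toward the lowest instance index
and zero-range features get weight zero. Ranges come from the training
split only — the held-out images never influence normalization, weights
or the selected set. The label is the five-class quadrant by default
(configurable), and k defaults to 5.

Per-participant weights are aggregated across the cohort by the
per-feature median; features with strictly positive median form the
optimal set (`optimal_feature_set()`), ordered by descending median.

### What selection on synthetic cohorts does and does not show

A structural property of per-window relevance estimation on contiguous
physiological recordings deserves emphasis. Adjacent 0.5-s windows are
near-duplicates in every slowly varying feature (the 0.1 Hz-low-passed
SCL, and especially the rolling-buffer HRV features, which share 29 of 30
intervals), so a window's nearest hits are almost always its temporal
neighbours. Any feature that is temporally smooth — whether or not it
carries class information — then shows smaller hit differences than miss
differences and receives a small positive weight. A label-shuffle control
(randomizing quadrants at the image level) reproduces the effect, and
injected i.i.d. noise features do not show it. In addition, an
event-locked tonic class effect unavoidably leaks a small class-patterned
component through the 0.1 Hz high-pass into the phasic stream, because a
15-s stimulus response has spectral content near the filter corner.

Consequently, on the synthetic cohort the median-positive rule retains
the thirteen genuinely modulated features (seven SCL features, HR
mean/min/max, SDNN, RMSSD, respiration rate) *plus* around five smooth
phasic statistics with small positive medians (~+0.005 to +0.015,
an order of magnitude below the modulated features), typically 18 in
total. The point-discrete phasic features (`N_peaks`, `PA_mean`,
`PA_std`) and the window-lag-anti-correlated `HR_std`/`HR_max_minus_min`
correctly fall out. Passing selection tests on this generator therefore
demonstrates recovery of modulated channels and rejection of discrete
noise features — not a sharp zero-threshold separation of smooth null
features, which this study design cannot deliver on continuous data.

## Classifiers and evaluation

Four supervised algorithms are wrapped behind one interface
(`fit_affect_model()`): k-nearest neighbours (k = 5), support vector
machines with cubic-polynomial and Gaussian kernels (one-vs-one for
multi-class, unit box constraint, kernel coefficient 1/23 after
z-scoring), and linear discriminant analysis. Features are z-scored with
training statistics stored in the model. KNN's k, the SVM box constraint
and the kernel width are not dictated by the method and are exposed as
configuration. For LDA only, features that are (near-)constant within
every training class are dropped at fit time: they carry no discriminant
information and make the within-class covariance singular.

Evaluation is leave-one-image-per-class-out (`loio_split()`): one image
per class, drawn by seed, contributes all of its windows to the test set,
so train and test never share a stimulus. Accuracy is the confusion-matrix
trace over the total; the F-score is the macro average of per-class
harmonic precision/recall means, appropriate for the balanced image
design. Classification is per 0.5-s window.

Estimation time (`measure_estimation_time()`) is the wall-clock span of
the full real-time path for one window: slicing a trailing 15-s raw
context, filtering and decomposition, beat detection, extraction of only
the model's features, and prediction. Reducing the feature set genuinely
reduces work (e.g. dropping the peak-statistics group skips SCR peak
detection), which is why the reduced-set timing is asserted as an
ordering, never as absolute milliseconds — absolute values depend on the
host.

Per-participant accuracies are compared across algorithms by pairwise
one-way ANOVA with the Bonferroni-corrected threshold
$p_m = 0.05/6 \approx 0.008$ (`compare_models()`).

## The synthetic cohort generator

`default_protocol()` draws the session: a 240-s rest baseline, then two
passes over the cluster order LAHV, HALV, HAHV, LALV, N with five images
per cluster; each image is preceded by a 5-s blank, shown for 15 s and
followed by a self-assessment gap drawn around 8.7 s (session ≈ 35 min).
Synthetic database ratings are drawn uniformly inside each cluster's
quadrant region (outside the neutral box for the four affective
quadrants). Because the real image set's ratings are not public, images
get fresh synthetic ratings per draw.

`simulate_subject()` renders the channels. The tonic conductance is the
subject baseline (uniform 2--10 µS) plus a slow drift (60-s knots,
sd 0.01 µS) plus per-image responses with a 12-s raised-cosine attack and
30-s exponential release — slow, C¹ kinetics are physiologically sensible
for tonic level shifts and keep the response's energy below the 0.1 Hz
tonic/phasic split. Phasic activity is a homogeneous Poisson train of
non-specific SCRs (3/min, a typical seated-rest rate) with bi-exponential
kernels (0.75 s rise, 2 s decay) and exponentially distributed amplitudes
(mean 0.3 µS), plus 0.015 µS sensor noise; by default phasic statistics
receive no class effect. The ECG is a train of Gaussian R bumps driven by
an AR(1) inter-beat process whose mean tracks the target heart rate and
whose stationary spread equals the active quadrant's SDNN; the AR
coefficient is set from the RMSSD/SDNN ratio (0.7). Respiration rate is
the subject baseline plus the quadrant effect plus breath-scale
variability (8-s knots, sd 0.25).

The default effect magnitudes are generator policy, chosen once on
physiological grounds: relative to neutral, tonic level
+0.9/+0.55/+0.1/+0.3 µS and slope +0.03/+0.02/0/+0.007 µS/s
(HAHV/HALV/LALV/LAHV), heart rate +10/+4/−4/−8 bpm (arousal raises it,
valence signs the magnitude), SDNN 28/32/50/56 ms against 42 ms at rest
(arousal suppresses variability), respiration +3.5/+2.5/+0.2/+1
breaths/min. Per-subject gain multipliers (uniform 0.7--1.3) and the
baseline draws provide inter-subject variability. Self-reports are the
true ratings with ±1 integer jitter per axis and a 10% chance of a
diagonal flip, which exercises the consistency filter at roughly the
rate it would fire on inattentive raters.

What the generator does *not* emulate: real ECG morphology (P/T waves),
motion artifacts, habituation of phasic responses across the session,
respiratory sinus arrhythmia coupling, and rater idiosyncrasies beyond
the flip/jitter model. Tests passing on this cohort show the pipeline's
mechanics and its recovery behaviour under known ground truth; they do
not certify accuracy levels on human data.

## Numerical choices and degenerate inputs

- Windows are half-open $[t, t+0.5)$; times are seconds from session
  start. Windows not fully covered by all streams, or whose IBI buffer
  holds fewer than three intervals, are skipped with a reported count.
- SDNN needs ≥ 2 intervals and RMSSD ≥ 3; below that they are `NA` and
  the window is skipped rather than imputed.
- The SCR peak threshold comparison is strict (> 0.03 µS), so a rise of
  exactly the threshold is not a peak.
- The neutral box boundary is closed: $(\pm 1, \pm 1)$ is neutral.
- Pairs of identical constant accuracy groups compare with F = 0, p = 1
  rather than `NaN`.
- Beat detection returns an empty vector on flat or sub-threshold
  signals; a constant dataset yields all-zero ReliefF weights.

## Problem sizes used in the test suite

The full study conditions are a 20-subject cohort with 50 images per
session. The acceptance checks run one such cohort (plus ten for the
selection-count mode in the acceptance script); module tests and the
replicate-based recovery checks use scaled sessions (2--3 images per
cluster, 3--8 subjects), which preserve the session structure while
keeping each replicate's cost at a few seconds. The vignette states these
sizes as the package's own choices for desk-scale verification.

## A worked example

```{r example, eval = FALSE}
library(physioaffect)
library(dplyr)

cohort <- simulate_cohort(n_subjects = 4, seed = 1)
prep <- preprocess_recording(cohort$S01)
features <- extract_features(prep)

features |>
  label_windows("FIVE_CLASS") |>
  loio_split(seed = 1) -> split

weights <- relieff(split$train, k = 5)
tidy(weights) |> arrange(desc(weight))

model <- fit_affect_model(split$train, "KNN")
evaluate_model(model, split$test, problem = "FIVE_CLASS")

# or the whole design in one call
study <- run_study(study_config(n_subjects = 4, seed = 1))
glance(study)
autoplot(study)
```

## Known limitations

- The generator's effect structure is deliberately simple (stationary
  per-quadrant offsets with fixed kinetics); it cannot represent
  habituation, context effects or mixed affective responses.
- Per-window classification inflates the effective sample size relative
  to per-image classification; per-image aggregation is available but not
  the default, and cross-window dependence should be kept in mind when
  interpreting significance tests on per-window results.
- The median-positive selection rule has no slack at zero; on continuous
  recordings, temporally smooth class-null features can cross it (see the
  selection section above).
- Frequency-domain HRV is out of scope by design: it needs 2--5 min
  windows, incompatible with 0.5-s estimation.
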