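# physioaffect

Real-time affective state estimation from wearable physiological
signals, in R.

People's positions on the valence–arousal plane (Russell's circumplex)
leave involuntary traces in autonomic signals: tonic and phasic skin
conductance, heart rate and its beat-to-beat variability, and
respiration rate. `physioaffect` implements a complete window-based
estimation pipeline for researchers in affective computing and
psychophysiology:

- **Signal model.** Multichannel recordings (GSR in µS at 51.2 Hz, ECG
  in mV at 250 Hz, respiration rate at 25 Hz) with a stimulus schedule
  carrying 1–9 valence/arousal ratings and participant self-reports,
  stored as diffable CSV-per-channel + JSON sidecar directories.
- **Preprocessing.** Zero-phase order-4 Butterworth filtering; 5 Hz
  denoising and complementary 0.1 Hz tonic (SCL) / phasic (SCR)
  decomposition of the conductance; R-peak detection on the native ECG
  with inter-beat-interval validation; linear resampling of all streams
  onto a shared 36.5 Hz grid; rest-baseline normalization of the level
  streams.
- **Features.** 23 named features per 0.5-s window — 15 electrodermal
  (SCL/SCR statistics, SCL derivatives, SCR peak count and amplitudes at
  the 0.03 µS threshold), 7 cardiac (HR statistics plus running
  SDNN/RMSSD over a trailing 15-s interval buffer), 1 respiratory.
- **Selection.** ReliefF (k nearest hits and misses under Manhattan
  distance on range-normalized features, empirical class priors,
  deterministic m = all) per participant; a cross-participant
  median-positive rule defines the global optimal feature set:

  $$W_A \leftarrow W_A - \sum_j \frac{d(A, R_i, H_j)}{mk}
    + \sum_{C \neq cls(R_i)} \frac{P(C)}{1 - P(cls(R_i))}
      \sum_j \frac{d(A, R_i, M_j(C))}{mk}$$

- **Classification.** Quadrant labels on the rescaled $[-4,4]^2$ plane
  (closed ±1 neutral box, 6.25% of the plane); four problems (high/low
  valence, high/low arousal, four-quadrant, five-class); KNN, cubic and
  Gaussian SVM, and LDA behind one interface with z-scoring,
  leave-one-image-per-class-out evaluation, macro F-scores, per-window
  estimation-time measurement, and pairwise ANOVA with Bonferroni
  threshold 0.05/6 ≈ 0.008.
- **Synthetic cohort.** A seeded generator emulating the stimulation
  protocol (4-min baseline; 10 clusters × 5 images in the order LAHV,
  HALV, HAHV, LALV, N, twice; 15-s images, 5-s blanks, ~8.7-s
  self-assessment gaps) with affect-dependent modulation of tonic
  conductance, heart rate, IBI variability and respiration rate, so the
  whole pipeline runs and is tested without human data.

Everything downstream of feature extraction is tibble-first and
pipeable, with broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()`/`plot_*()` functions.

## A worked example

```r
library(physioaffect)
library(dplyr)

cohort <- simulate_cohort(n_subjects = 4, seed = 1)
features <- preprocess_recording(cohort$S01) |> extract_features()

split <- features |> label_windows("FIVE_CLASS") |> loio_split(seed = 1)
tidy(relieff(split$train, k = 5)) |> arrange(desc(weight)) |> head(5)
#> # A tibble: 5 × 4
#>   feature   weight     k participant_id
#>   <chr>      <dbl> <dbl> <chr>
#> 1 RR_mean   0.206      5 S01
#> 2 SCL_max   0.193      5 S01
#> 3 SCL_mean  0.193      5 S01
#> 4 SCL_min   0.192      5 S01
#> 5 sDNN_mean 0.0930     5 S01
```

The weights say how well each feature separates nearest same-class from
other-class windows: here the respiration rate and tonic conductance
level carry most of the planted affect signal for this subject.

```r
model <- fit_affect_model(split$train, "KNN")
evaluate_model(model, split$test, problem = "FIVE_CLASS")
#> <affect_eval> KNN / FIVE_CLASS: accuracy 0.793, macro-F 0.793 on 150 windows
```

Accuracy is the confusion-matrix trace over the total count on held-out
images (chance level for five classes is 0.20); macro-F averages
per-class harmonic precision/recall means. `run_study(study_config())`
runs the full design — selection, all problems × algorithms × feature
sets, ANOVA comparisons and the per-sensor ablation — and
`report_study()` writes the result tables. A thin command-line wrapper
lives at `inst/cli/physioaffect.R` (`simulate`, `run-all`).

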