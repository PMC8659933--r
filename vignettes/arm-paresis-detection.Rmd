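---
title: "Detecting unilateral arm paresis from bilateral wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unilateral arm paresis from bilateral wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A stroke typically announces itself as a sudden, one-sided loss of motor
function. If both wrists carry an accelerometer bracelet, the asymmetry
between the two movement signals is a candidate biomarker: a paretic arm
moves less than the healthy one, at every grade of severity from mild
drift to complete paralysis. The clinically interesting question is not
whether the asymmetry is detectable over a day of recording — it is — but
how *short* a stretch of signal suffices, because the window length bounds
the detection delay and thus a patient's eligibility for time-critical
reperfusion treatment.

`armasym` implements this analysis end to end: a synthetic cohort
generator standing in for the (non-public) clinical recordings, the
preprocessing chain, sliding-window segmentation, asymmetry features,
classical and convolutional classifiers, and the statistical machinery for
comparing them.

## The synthetic cohort generator

No public recordings of this kind exist, so the generator is a first-class
part of the package and defines the study conditions for every test.

Each subject's arm is modelled as an 8-bit triaxial sensor at 32 Hz
(64 counts = 1 g) observing:

* a **gravity baseline** — a unit vector scaled to 64 counts that
  reorients (with a one-second ramp) after sufficiently large movements
  and is otherwise static;
* **activity bouts** — Poisson-arrival bursts (waking rate 4/min, sleeping
  rate 0.15/min within a 23:00–07:00 sleep window), each a 4–10 Hz carrier
  under a Hann envelope with log-normal duration (median 4 s) and
  log-normal peak amplitude around the subject's activity level (1 g,
  with ±20% between-subject spread). Bouts are shared between the arms;
  20% are unilateral;
* **sensor noise** — Gaussian with SD 0.15 counts, below the one-count
  quantisation step that rounding to int8 adds on top.

Paresis is a grade-dependent attenuation of affected-arm bout amplitudes:
0.7, 0.4, 0.15 and 0.0 for grades 1–4 on the arm-motor scale, monotone by
construction with grade 4 meaning "no movement". Cohorts draw grades at
the study population's proportions (9.5 / 25.0 / 42.9 / 22.6% for grades
1–4), right-sided paresis with probability 0.452, per-subject monitoring
durations spread up to an hour above the nominal value, and bracelet
start-time offsets uniform in ±30 s. Everyone, including controls, gets a
mild hand-dominance asymmetry (non-dominant arm gain 0.85–1.0, random
side): without it the control class is unrealistically symmetric and the
classification task trivial. Recordings end with ten minutes of
baseline-only "tail", emulating bracelets left running after the session.

Amplitude and rate defaults were chosen once, for realism at the signal
level (waking activity duty cycle of roughly a third, processed magnitudes
overwhelmingly below 1 g, a noise floor well below the 0.01 g tail
threshold); they were not calibrated to any reported performance number.

What the generator does **not** emulate: circadian structure beyond one
sleep window, off-wrist and artifact periods, hospital-environment
activity patterns (passive movement of a paretic arm by caregivers), or
device-specific noise spectra. Passing tests therefore demonstrate that
the pipeline recovers a *planted* asymmetry under controlled conditions —
synthetic cohorts separate more cleanly than clinical ones (held-out AUCs
saturate near 1), and no number computed here estimates clinical
performance.

Seeding is hierarchical: each subject's profile and signal derive from the
cohort seed and the subject's id, so enlarging a cohort leaves existing
subjects bit-identical.

## Preprocessing

Per arm: a fifth-order Butterworth high-pass at 3 Hz applied to each axis
independently (removing gravity and slow posture change), the Euclidean
magnitude, a moving average over 96 samples, subsampling by 48 (to
32/48 ≈ 0.67 Hz), and division by 64 so that 1 equals gravity.

Numerical choices worth recording:

* **Causal, single-pass filtering** is the default (a real-time wearable
  cannot look ahead); `zero_phase = TRUE` switches to forward–backward
  filtering. The causal filter's step response decays below 1e-6 only
  after about 3.2 s, so the package documents a 4 s warm-up; tests assert
  DC annihilation after it.
* The **moving average is causal and length-preserving**, with an
  expanding window over the first 95 samples; decimation keeps samples
  1, 49, 97, … A "valid-positions-only" average would shorten the series
  and yield 599 rather than the required 600 output samples for 15 min of
  input, so length preservation is forced by the 2 × 600 window-size
  contract.
* **Synchronisation** between the independently started bracelets
  minimises the *mean* absolute inter-arm difference over the overlap, by
  exhaustive search over integer lags within ±300 s at the processed
  rate. The mean (not the raw sum) avoids trivially favouring short
  overlaps. Sub-sample precision is pointless after 48-fold decimation,
  and searching at the processed rate keeps the search cheap. Ties prefer
  the smallest magnitude lag.
* **Tail trimming** is automated with an explicit rule — remove a trailing
  run of at least 10 min during which both arms stay below 0.01 g —
  because the original visual inspection is not reproducible. A recording
  that is quiet throughout is rejected rather than silently emptied.

## Windows and features

Processed pairs are cut into windows of 15, 30, 45, 60, 90 or 120 minutes
(600–4800 samples) with 20% overlap between adjacent windows; the stride
is `round(0.8 L)` and a trailing partial window is discarded. Every window
inherits its subject's id and label, and subject identity is respected by
every split downstream.

Fourteen features per window: mean, median, standard deviation and maximum
of each arm; their arm1 − arm2 differences; and the fraction of samples in
which one arm exceeds the other by at least 0.01 g (each direction).
Conventions fixed here: the exceedance count is divided by the window
length in samples (unit-free, bounded in [0, 1]); the inequality is closed
(≥ 0.01); standard deviations use the population divisor L; even-length
medians average the central pair. Feature extraction is exactly
equivariant under swapping the arms — per-arm statistics exchange,
differences negate, the two fractions exchange — which is what makes
arm-swap augmentation implementable directly on feature matrices
(`swap_features()`).

## Models and confidence scores

Three classical families operate on the features: an RBF-kernel SVM
(`e1071`), k-nearest neighbours (`class`), and a random forest
(`randomForest`). Every training set is augmented with its arm-swapped
copy so no model can learn a left/right preference. Confidence scores
follow each family's native notion: the signed SVM decision value, the
fraction of stroke-labelled neighbours, the fraction of stroke-voting
trees. The random-forest backend implements Gini impurity only, so the
split-criterion axis of the grid is fixed at `"gini"`; its
minimum-samples-to-split parameter maps to a terminal node size of
`ceiling(mss / 2)`.

The reference deep model is a three-block 1-D fully convolutional network
(kernel sizes 8/5/3, batch normalisation, ReLU, global average pooling,
two-way softmax) trained with Adam on raw two-channel windows,
average-pooled by a configurable factor beforehand. The published design
uses channel widths 128/256/128; the package defaults to 16/32/16, which
train in seconds on a single core — the architecture, protocol and all
bookkeeping are unchanged by the width. The training protocol is: a fixed
budget of 100 epochs, the model state with the highest validation accuracy
kept (validation accuracy taken at the 0.5 threshold on the positive
output — the convention is not dictated elsewhere, so it is fixed and
tested here), and the learning rate halved whenever 20 consecutive epochs
bring no improvement. The schedule is factored out as a pure function
(`deep_schedule()`) so the checkpoint and halving rules are testable with
injected accuracy traces.

Hyperparameter grids (`default_grids()`) span each family's operating
range at desk scale: C ∈ {0.1, 1, 10, 100} × γ ∈ {0.01, 0.1, 1};
k ∈ {3, 5, 11, 21}; 100 or 300 trees × minimum split {2, 5, 10}; initial
learning rate {1e-3, 1e-4} × pooling factor {1, 2, 4, 8}.

## Cross-validation, ensembling and comparison

Subjects are split into five stratified groups of about 20% each; one is
held out as the test set. Grid search runs four-fold cross-validation over
the remaining four groups, scoring each configuration by mean validation
AUC. Because the deep models consume their validation folds as a stopping
criterion, no clean retraining set remains; the final model for *every*
family is therefore the ensemble of the four fold models, averaging their
confidence scores. SVM decision values are unbounded margins and would
dominate a raw average, so each member's scores are min-max rescaled over
the scored batch first — rank-preserving per member, and a documented
choice where the original procedure is unstated.

ROC curves sweep the unique scores; AUC is the trapezoidal integral, which
equals the pairwise concordance probability with ties counted one half
(asserted against a brute-force oracle). The operating point is the curve
point nearest the ideal corner, ties resolved toward the lowest threshold.

For the model comparison, the held-out subjects are split into `n_parts`
stratified parts — split by subject, never by window, to avoid leakage;
the parts × window-lengths AUCs form the dataset axis of a Friedman rank
test (chi-square form with tie correction; the F refinement and a
permutation p-value are options), followed by a post-hoc Nemenyi test with
`CD = q_alpha sqrt(k (k+1) / 6N)`, q from the studentized-range table at
infinite degrees of freedom divided by √2. `plot()` on the experiment
draws the standard critical-difference diagram.

## Problem sizes

The test suite and the acceptance script run, as the package's own desk
scale: a 30 + 36 subject cohort of 8-hour recordings for parameter
recovery (window lengths 15/30/60/120 min, five test parts), 100 seeded
simulations for sync-shift recovery, 1000-window batches for the exact
feature and AUC property checks, and a k = 3, N = 8 exact-enumeration
oracle for the Friedman permutation test. With five test parts a
five-subject part is the smallest that keeps both classes represented;
ten parts (as in a full-size cohort) are used whenever the test group is
large enough.

## Known limitations

* Synthetic separability: the generator's group effect is strong enough
  that held-out AUCs saturate; comparisons *between* families on
  synthetic cohorts are therefore mostly uninformative ties.
* The Friedman parts within one window length share the trained ensemble,
  and parts across window lengths share subjects, so the "datasets" of
  the rank test are not independent — a property inherited from the
  original design, not introduced here.
* Only the accelerometer channel of the bracelet is modelled; EDA,
  temperature and PPG are out of scope, as are artifact/off-wrist
  detection and resampling to other device rates.
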