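---
title: "Methods: wearable patient monitoring and counterfactual well-being support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable patient monitoring and counterfactual well-being support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pulseman implements the data-driven core of a personal health system for
patients with congestive heart failure: continuous cuffless blood-pressure
(BP) estimation from a wrist photoplethysmogram (PPG), physical-activity
recognition from wrist acceleration, psychophysiological profile
recognition from speech prosody and heart-rate variability, and a
counterfactual recommender that proposes minimal changes to modifiable
conditions (e.g. room temperature) predicted to flip a patient's
self-reported feeling of health from bad to good. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## PPG signal quality and cardiac-cycle screening

A wrist PPG is an optical measure of blood-volume pulsations: one cardiac
cycle per heartbeat, a steep systolic upstroke to the systolic peak,
followed by a diastolic decay, with diastolic valleys separating beats.
Wrist recordings are noisy — motion artifacts, contact-pressure changes and
low sensor rates — so everything downstream depends on screening out bad
cycles. The chain in `ppg_preprocess()` is:

1. **Normalization** to zero mean and unit population SD, making
   amplitudes comparable across sensors and gains (`normalize_signal()`).
2. **Hampel despiking** (`hampel_filter()`): a sample deviating from its
   local median by more than 3 robust SDs (1.4826 x the local MAD) is
   replaced by that median. The window is 11 samples (`half_window = 5`);
   at the record edges the window is truncated so every sample is
   screened. Outliers are replaced rather than deleted because the
   subsequent filter assumes uniform sampling, and the MAD-based spread is
   used because a plain SD is itself corrupted by the spike it should
   detect.
3. **Zero-phase Butterworth band-pass**, 0.5–4.0 Hz, order 4
   (`bandpass_filter()`), retaining 30–240 bpm cardiac content while
   removing baseline drift and high-frequency noise. The filter is applied
   forward and backward so cycle landmarks are not shifted in time; the
   effective amplitude response is the squared one-pass response, and
   `butter_bandpass_gain()` provides its analytic value (at the
   bilinear-prewarped frequency) for verification. Before filtering, the
   signal is padded with edge reflections (about three periods of the low
   cutoff) so start-up transients do not leak into the retained samples.
4. **Cycle detection** (`detect_cycles()`): the first derivative is
   scanned for prominent maxima — the steepest systolic upslopes —
   separated by a 0.25 s refractory period; the systolic peak is the
   signal maximum after each upslope; the diastolic valley is the minimum
   between consecutive peaks; cycles run valley to valley and must last
   0.25–2.0 s (30–240 bpm). Landmarks are refined to sub-sample precision
   by parabolic interpolation: at wristband rates (64 Hz) the sample grid
   quantizes durations by ~16 ms, which would otherwise dominate the
   per-beat variability of timing features.
5. **Template screening** (`build_templates()`, `score_cycle_quality()`):
   the cycle sequence is traversed with a non-overlapping window of 10
   cycles; each cycle is resampled to 64 points and the window template is
   their pointwise **median**. The median (rather than the mean) is
   deliberate: with realistic artifact rates a mean template is itself
   contaminated — sign-inverted cycles cancel the pulse shape and noise
   bursts inject variance — which would reject clean cycles in unlucky
   windows. The median tolerates up to half the window being corrupted and
   coincides with the mean for the degenerate one- and two-cycle windows.
   Each cycle is then compared with its template on three metrics:
   Pearson correlation of the waveforms, the Euclidean distance between
   the z-scored waveforms (amplitude-invariant shape distance, equal to
   sqrt(2(1 − r))), and the relative deviation of its duration from the
   window median. A cycle is kept when r ≥ 0.9, distance ≤ 0.5 and
   duration deviation ≤ 0.25 (all configurable). Comparison happens on
   z-scored waveforms because PPG amplitude varies with contact pressure
   and perfusion and carries little morphology information; quality is a
   statement about shape.

## Cuffless BP estimation

Per kept cycle, 35 features are computed (`extract_cycle_features()`):

* **Temporal (17)**: duration, systolic upstroke time, diastolic time,
  upstroke fraction, amplitude, widths at 25/50/75% amplitude, area,
  half- and quarter-decay times, a log-linear decay-rate estimate over the
  20–80% post-peak region, diastolic area fraction, and the extrema of the
  first and second derivatives. Times use the sub-sample refined
  landmarks; widths and decay times use interpolated level crossings.
* **Spectral (7)**, over a window extending 5 s before and after the
  cycle (clipped at record edges, minimum 2 s): total 0.5–4 Hz power,
  relative power in 0.5–1.5/1.5–2.5/2.5–4 Hz (summing to one), dominant
  frequency, spectral entropy, harmonic ratio.
* **Accelerometer (10)**: per-axis mean/SD, magnitude mean/SD, motion
  intensity, and a validity flag (all-zero sentinel when no accelerometer
  sample covers the window) — motion context matters because the
  cardiovascular response differs under activity.
* **Heart rate** from the cycle duration.

In the session feature table (`ppg_session_features()`) the temporal and
heart-rate features are additionally smoothed with a 21-beat rolling
median within contiguous runs of cycles. BP changes over minutes while
cycles arrive about once per second, and the cuff ground truth is anyway
attributed to the surrounding ±30 s of signal, so beat-scale measurement
noise — including a slow beat-to-sample-grid phase artifact typical of
low-rate sensors — can be suppressed without blurring the BP signal. The
smoother never crosses gaps larger than 5 s.

Cycles are paired with the nearest cuff reading within ±30 s
(`pair_with_ground_truth()`, ties to the earlier reading) and fed to
paired SBP/DBP regressors (`train_bp_model()`): a training-mean dummy
baseline, a decision tree, k-nearest neighbours (k = 5 on standardized
features), radial-kernel support-vector regression, and a random forest
(500 fully grown trees, mtry = p/3 — the standard regression-forest
defaults). Features are standardized with training-set statistics only;
predictions are clipped to 30–300 mm Hg.

Two evaluation protocols mirror the two deployment settings
(`evaluate_loso()`, `evaluate_personalized()`): leave-one-subject-out for
a general model, with the held-out subject never seen in training; and a
personalized chronological 70/30 split at *reading* granularity — readings
are ordered in time, the earliest 70% (with all their paired cycles) form
the training set, so no reading's cycles straddle the split and training
strictly precedes testing. Both report the mean absolute error (MAE,
mm Hg) against the dummy baseline; beating the dummy is the meaningful
claim, since the dummy encodes the trivial "predict this person's average
BP" strategy.

## Physical-activity recognition

The tri-axial wrist stream is low-pass filtered at 10 Hz to remove sensor
noise; the gravity component is its 0.3 Hz low-pass and the dynamic
(human-motion) component the difference, an exact reconstruction by
construction (`split_components()`). The stream is segmented into
non-overlapping 2 s windows (`segment_windows()`, trailing partial
dropped), and 65 documented features are computed per window
(`extract_activity_features()`): ten distribution statistics per dynamic
axis and magnitude, velocity-change and kinetic-energy proxies, peak
counts (prominence ≥ 0.05 g) and mean-crossing counts, inter-axis
correlations, and gravity orientation (per-axis means and inclination
angles). Skewness and kurtosis of constant windows are defined as 0 to
avoid NaN propagation. A random forest over the closed 10-activity label
set (rest, standing, walking, Nordic walking, running, exercise, eating,
washing, chores, hand activities) is trained per fold and evaluated
leave-one-subject-out, pooling fold predictions into one confusion matrix
from which per-class precision, recall and F-measure and their macro
averages are computed (`evaluate_activity_loso()`); a class absent from
the pooled truth is excluded from the macro averages rather than
propagated as NaN.

## Psychophysiological profiles

Speech from a structured interview and wristband cardiac data are fused
early into one feature vector. Audio is DC-removed and RMS-normalized
(`preprocess_audio()`), so all speech features are gain-invariant. On
25 ms frames with 10 ms hop, the front-end (`extract_speech_features()`)
computes pitch by autocorrelation (50–500 Hz search band, voicing
threshold 0.3, parabolic lag interpolation, unvoiced frames excluded), 13
MFCCs (26-filter mel bank, DCT-II), and smoothed log energy (5-frame
moving average); each base feature is summarized by mean, SD, range, max
and min — 75 features. Cardiac features are the mean heart rate and RMSSD,
the root mean square of successive beat-to-beat interval differences
(`compute_rmssd()`), with intervals outside 250–2400 ms rejected. The
3-class model (motivated / anxious / depressed) defaults to an SVM, with
naive Bayes, a multilayer perceptron and a random forest available, and is
evaluated LOSO against the majority-class baseline. Note that under LOSO
with perfectly balanced classes the training-majority baseline is
degenerate (it always names a class the held-out subject does not have),
which is the correct definition, just a conservative comparator. Each
recognized profile maps to its cognitive-dissonance message principle
(`select_cbt_principle()`): forced-compliance consequences for motivated,
free choice for anxious, effort justification for depressed patients.

## Counterfactual well-being recommendations

From tabular well-being records (physiological + environmental features,
good/bad label) a random-forest feeling-of-health classifier is trained
(`train_health_model()`; held-out accuracy on a stratified 80/20 split is
reported). Features are partitioned (`partition_features()`) into
*modifiable* (given by configuration), *correlated* (absolute Pearson
correlation with some modifiable feature ≥ 0.3) and *uncorrelated*; each
correlated feature gets an OLS model on all modifiable features
(`fit_correlated_models()`, pseudoinverse with a warning when rank
deficient). `propagate()` applies a candidate modification and moves each
correlated feature by the *difference* of its linear predictions at the
modified and original modifiable values — residual-preserving, so the zero
modification is exactly the identity; the alternative (replacing the
correlated value by its prediction) would modify records even when
nothing changes.

The search (`recommend()`) minimizes two objectives: the modification
**volume** — the sum of |delta| normalized by each feature's training
range, a unit-free size — and the **number of changed features**, since
fewer, smaller changes are easier to follow. A candidate is *admissible*
when the classifier predicts "good" for the propagated record. The
prediction rule is deliberately a pure function of the inputs — a
probability forest with good declared iff P(good) > 0.5, an exact tie
counting as bad — because a majority-vote forest breaks exact vote ties
randomly at predict time, which would make the admissibility of boundary
candidates irreproducible between calls. The optimizer
is NSGA-II: fast non-dominated sorting with crowding distance
(`nondominated_sort()`), binary tournaments under constrained domination
(any admissible candidate outranks any inadmissible one), simulated binary
crossover (eta = 15, p = 0.9) and polynomial mutation (eta = 20,
p = 1/n). Because real-coded variation essentially never produces exact
zeros, the mutation includes an explicit gene-zeroing move (p = 0.2 given
mutation) and the population is initialized sparsely (each gene active
with p = 0.3); without this, single-feature recommendations would be
unreachable and the n-changed objective meaningless. Population 100,
100 generations by default. The returned front contains only admissible,
mutually non-dominated, deduplicated modifications; a record already
predicted good returns an empty front with status `already-good`, and a
failed search returns `no-suitable-modification` — both expected outcomes,
not errors. Note that when two different single-feature modifications can
both flip the prediction, only the smaller-volume one survives Pareto
dominance (the other is dominated at equal n-changed).

## Synthetic data: what it emulates, and what it does not

No public dataset accompanies this problem, so every component is
validated on generated data with exact ground truth
(`gen_ppg_session()`, `gen_cycle_set()`, `gen_activity_session()`,
`gen_wellbeing_dataset()`, `gen_profile_dataset()`); all generators
require a seed and are bit-reproducible.

The PPG generator emits one two-lobe pulse per beat on a normalized phase
axis: a sine quarter-wave rise over a fraction *u* of the cycle, then an
exponential decay (normalized to return to the valley) plus a small
dicrotic bump. The morphology-to-BP mapping is the generator's documented,
invented stand-in for vascular physiology — *not* a validated hemodynamic
model: u = 0.42 − 0.002 (SBP − 120) and decay constant
tau = 0.45 − 0.004 (DBP − 80), both clamped. BP trajectories are
piecewise linear, cuff readings are emitted every 30 simulated minutes,
Gaussian sensor noise is added (5% of pulse amplitude in the study
conditions), and artifacts corrupt whole cycles as noise bursts
(SD 0.5) or sign inversions. Activity regimes are per-class documented
signal families (gravity plus noise at rest; 2/3 Hz arm-swing sinusoids
for walking/running; intermittent wrist rotations for eating; broadband
bursts for chores; per-subject lognormal amplitude/frequency factors of
about 10%). Well-being tables draw Gaussian marginals with configurable
cross-correlations and label records by a declarative rule with optional
label flips. Profile data are per-class Gaussian shifts of summary
features plus interval series matching each subject's RMSSD target.

Passing tests on these fixtures demonstrates that the *algorithms* are
correct and recover known structure under realistic noise; it does not
demonstrate clinical accuracy on real wristband data, where morphology-BP
coupling is weaker, person-specific and confounded, artifacts are more
diverse, and labels are imperfect. The problem sizes used by the test
suite and the acceptance script (a 4 h personalized session at 64 Hz with
9 readings, 2 h sessions for three LOSO subjects, six synthetic subjects
by five activity regimes, 30 profile subjects, 400-record well-being
tables with 20 optimized bad records) were chosen as the smallest scales
at which the statistical claims are stable.

## Numerical choices and known limitations

* Filtering uses edge-reflection padding before forward-backward
  application; gains are verified against the analytic response at
  prewarped frequencies to 1e-2 relative.
* Cycle detection assumes a dominant upslope per beat (threshold 0.3 x
  max derivative); pathological waveforms (pulsus alternans, severe
  arrhythmia) would need a different detector.
* Template windows at the end of a record may hold fewer than 10 cycles;
  a trailing partial window still yields a template (n >= 1).
* The quality thresholds (0.9 / 0.5 / 0.25) are configurable stand-ins:
  the source system reports using "several metrics" without values.
* kNN and SVR operate on standardized features; the rank-deficient OLS
  fallback uses the Moore-Penrose pseudoinverse; ties in the pairing step
  go to the earlier reading; ties in reported fronts are ordered by
  (n_changed, volume).
* The recommender treats the classifier as ground truth; its
  recommendations are counterfactuals under that model, not causal
  claims.
* Audio I/O is limited to 16-bit PCM mono WAV; the speech front-end is
  the package's own implementation (autocorrelation pitch, mel filter
  bank) with fixed frame parameters documented above.
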