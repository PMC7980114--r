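# pulseman

Patient-monitoring and decision-support methods for self-management of
congestive heart failure, as an R package: continuous cuffless blood
pressure (BP) from a wrist photoplethysmogram (PPG), physical-activity
recognition from wrist acceleration, psychophysiological profile
recognition from speech and heart-rate variability, and a counterfactual
recommender that searches for the smallest change to a patient's
modifiable conditions predicted to flip their feeling of health from bad
to good. It is written for researchers and engineers building or
evaluating mHealth monitoring pipelines who need tested, reproducible
reference implementations rather than device firmware.

## What is inside

**PPG quality screening and BP estimation.** The PPG is normalized,
despiked with a Hampel filter (3 robust SDs over an 11-sample window),
band-passed with a zero-phase 4th-order Butterworth (0.5–4 Hz), and
segmented into valley-to-valley cardiac cycles via a first-derivative
transformation. A sliding 10-cycle window yields a robust waveform
template, and each cycle is kept only if it matches its template
(correlation ≥ 0.9, z-scored shape distance ≤ 0.5, duration deviation
≤ 0.25). Kept cycles yield 35 temporal/spectral/accelerometer/heart-rate
features; cuff readings are attributed to the surrounding ±30 s of signal
and paired regressors (dummy mean, decision tree, kNN, SVR, random
forest) estimate SBP and DBP. Evaluation is leave-one-subject-out (LOSO,
one fold per subject) or personalized chronological 70/30 at reading
granularity, reporting MAE in mm Hg against the training-mean dummy:

MAE = mean |ŷ − y|,  dummy ŷ ≡ mean(y_train).

**Activity recognition.** Gravity/dynamic separation (0.3 Hz / 10 Hz
low-passes), 2-s windows, 65 documented features, a random forest over
10 activities, and a LOSO harness reporting per-class precision, recall,
F-measure (harmonic mean) and macro averages from the pooled confusion
matrix.

**Psych profiles.** RMS-normalized audio → pitch (autocorrelation), 13
MFCCs and smoothed log-energy statistics (75 features), plus heart rate
and RMSSD = sqrt(mean((RR_{i+1} − RR_i)^2)); a 3-class model
(motivated / anxious / depressed) evaluated LOSO against the majority
baseline, and the fixed mapping of each profile to its
cognitive-dissonance message principle.

**Well-being recommender.** A random-forest feeling-of-health classifier;
features partitioned into modifiable / correlated (|Pearson r| ≥ 0.3 with
a modifiable feature, each with an OLS propagation model) / uncorrelated;
NSGA-II minimizing (volume, n_changed) where
volume = Σ |Δx_i| / range_i, under the admissibility constraint that the
classifier predicts "good" for the propagated record.

**Synthetic data.** Seed-deterministic generators with full ground truth
for all four components (PPG with a documented morphology→BP mapping,
scripted activity regimes, rule-labeled well-being tables, class-shifted
profile data), so the whole package is testable offline.

## Worked example

Ten minutes of synthetic wrist PPG with drifting BP, cuff readings every
2 minutes, 5% sensor noise and 3 artifact cycles/minute:

```r
library(pulseman)

ses  <- gen_ppg_session(duration = 600, hr = 72, sbp = c(118, 132),
                        dbp = c(76, 86), noise_sd = 0.05, artifact_rate = 3,
                        reading_interval = 120, seed = 42)
prep <- ppg_preprocess(ses$ppg)
sprintf("detected %d cycles, kept %d (%.1f%%)",
        length(prep$cycles), sum(prep$kept), 100 * mean(prep$kept))
#> "detected 735 cycles, kept 671 (91.3%)"

feats <- ppg_session_features(prep, accel = ses$accel, readings = ses$readings)
inst  <- pair_with_ground_truth(feats, ses$readings)
evaluate_personalized(inst, algorithm = "random_forest", seed = 1)
#> <bp_eval> random_forest (chronological folds)
#>   MAE SBP 4.58 mm Hg (dummy 6.44), MAE DBP 3.29 mm Hg (dummy 4.60)
```

The screen discarded 8.7% of cycles — essentially the injected artifacts —
and the personalized forest beats the "predict this person's average BP"
dummy on both targets on the held-out (later) readings.

A recommendation for a patient record predicted "bad" (here the true rule
behind the synthetic data is good iff temperature ≤ 26 °C and humidity
≤ 65 %RH):

```r
ds    <- gen_wellbeing_dataset(400, rule = "temperature <= 26 & humidity <= 65",
                               noise = 0.02, seed = 7)
model <- train_health_model(ds$records, seed = 7)      # held-out accuracy 97.5%
part  <- fit_correlated_models(ds$records,
           partition_features(ds$records, c("temperature", "humidity")))
rec   <- ds$records[which(predict(model, ds$records) == "bad")[1],
                    setdiff(names(ds$records), "label")]
sprintf("record: temp %.1f C, humidity %.1f %%RH", rec$temperature, rec$humidity)
#> "record: temp 22.7 C, humidity 82.4 %RH"

recommend(rec, model, part,
          bounds = list(temperature = c(-10, 10), humidity = c(-30, 30)),
          seed = 7)
#> <pareto_front> status: ok, 1 solution(s)
#>  delta_temperature delta_humidity volume n_changed
#>                  0         -17.51  0.255         1
```

The record is too humid; the front proposes lowering humidity by about
18 %RH (a quarter of its observed range) and touching nothing else, and
the modified record is verified admissible by the classifier.

And a one-liner: `compute_rmssd(c(812, 790, 804, 821, 797))` returns
`19.65` ms, the short-term heart-rate variability of those five beats.

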