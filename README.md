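# glucowear

Analysis tools for 28-day digital metabolic-health programs that combine a
continuous glucose monitor (CGM), a heart-rate wearable, and self-logged
meals, activity and body weight. The package is aimed at biostatisticians
and digital-health researchers who need a *tested, fully reproducible*
version of this analysis stack: because real program cohorts are typically
proprietary, every stage can be exercised on synthetic cohorts whose
ground truth is known, so each estimate has an oracle.

## What it implements

* **Synthetic cohorts** (`generator_config()`, `generate_cohort()`) —
  participants in three glycemic categories (healthy, prediabetes,
  non-insulin-treated T2D) with meal-driven glucose excursions
  (gamma-like kernel, peak `amplitude · carb_g · max(0, 1 − fiber_atten ·
  fiber_g)`), a low-amplitude circadian term, diurnal heart rate with
  exercise bouts, meal logging whose adherence decays over the program,
  contiguous CGM signal-loss gaps, and an optional injected
  behavior-change effect (end-window carbohydrate cut, activity increase)
  with closed-form expectations for recovery tests.
* **Cohort quality control** (`qc_thresholds()`,
  `select_analysis_sets()`) — the inclusion rules that define the
  analysis subsets: ≥70% CGM coverage on ≥half the days of both QC
  windows, ≥2 meal logs on every day of the first 7 and last 14 days,
  ≥20 h/day heart-rate capture, weight measurements in both windows, and
  the "good logging day" rule (≥2 logs within a 16-h window spanning
  ≥4 h, ≥1600 kcal).
* **Glycemic metrics** (`time_in_range()`, `gmi()`, `count_events()`,
  `coefficient_of_variation()`, `subgroup_deltas()`) — time in range
  (70–140 mg/dL, or 70–180 for T2D), the glucose management indicator
  `GMI(%) = 3.31 + 0.02392 · mean glucose`, lost-time-adjusted excursion
  events per day (>140/>180/>250/<70 mg/dL), glycemic variability (CV),
  and baseline-defined subgroup changes (TIR < 90%, TIR < 70%, GMI > 6%,
  GMI > 7%).
* **Behavior metrics** (`nutrient_summary()`,
  `adjusted_activity_minutes()`, `hr_above_threshold_minutes()`,
  `weight_change()`) — macronutrient-to-calorie ratios over good logging
  days (4 kcal/g for carbohydrate, sugar, protein; 9 kcal/g for fats),
  activity minutes adjusted for app-interaction frequency, HR > 110 bpm
  minutes/day, and weight change with baseline-weight strata.
* **Probabilistic glucose prediction** (`cgp_config()`, `cgp_train()`,
  `predict_postprandial()`, `vcgm_rollout()`, `cgp_ablation()`,
  `per_user_tune()`) — an LSTM + dense network over 15-min feature frames
  (glucose, heart rate, exercise, time-of-day sin/cos, meal nutrients)
  with a categorical head over a 100-point glucose grid, trained by
  negative log-likelihood with Adam and scheduled-sampling feedback.
  Supports 2-h post-meal forecasts, fully autoregressive "virtual CGM"
  day rollouts with percentile bands, ablation-based feature importance,
  and per-user random-search tuning.
* **Food recommendation** (`recommend_foods()`, `healthiness_score()`,
  `identify_spiking_foods()`, `lever_plan()`) — similarity matching on
  per-100-kcal nutrient densities, blacklist removal, carbohydrate/fiber
  healthiness ranking and cleanup; spiking-food identification by
  incremental 2-h post-meal AUC; and the five intervention levers
  (spiking foods, calorie target via Mifflin-St Jeor, fiber goal by sex,
  post-meal activity, 16-h fasting target).
* **Statistics** (`paired_t()`, `cohort_report()`,
  `effect_recovery_study()`, `type1_calibration_study()`) — paired
  baseline-versus-end t-tests with Shapiro–Wilk normality flags, the
  assembled report tables, and simulation studies for effect recovery,
  power and type-I calibration.

## Worked example

```r
library(glucowear)

cfg <- generator_config(
  n_participants = 60,
  effect = list(carb_reduction = 0.30,   # 30% fewer carbs from day 15
                activity_increase = 0.25,
                start_day = 15),
  seed = 42)
cohort <- generate_cohort(cfg)
qc     <- select_analysis_sets(cohort)
report <- cohort_report(cohort, qc)
report
#> <cohort_report> n=60 (glucose 29, weight 14, diet 29)
#> significant overall changes:
#>   tir_pct        delta +5.614 (p=6.5e-19)
#>   gmi_pct        delta -0.090 (p=2.3e-18)
#>   mean_glucose   delta -3.763 (p=2.3e-18)
#>   cv_pct         delta -5.083 (p=4.1e-20)
#>   events_140     delta -1.040 (p=4.1e-10)
#>   events_180     delta -0.502 (p=5e-09)
```

Of the 60 generated participants, 29 satisfy the CGM, meal-logging and
heart-rate inclusion rules (the glucose analysis set). Because the
generator injected a 30% end-window carbohydrate reduction, the paired
comparisons recover what the intervention should produce: time in range
rises by ~5.6 percentage points, mean glucose and GMI fall, glycemic
variability drops, and >140/>180 mg/dL excursion events become rarer.
Subgroup tables (`report$subgroups`) show larger TIR gains in the
suboptimal-control subgroup (baseline TIR < 90%), and
`report$nutrient_changes` shows the negative carbohydrate-ratio change
the effect implies.

Training the glucose predictor on one well-logged participant:

```r
rec  <- generate_participant(
  generator_config(noise_sd = 0, signal_loss_fraction = 0,
                   adherence_start = 1, adherence_end = 1, seed = 11),
  "healthy", 1)
mcfg <- cgp_config(lstm_units = 16, epochs = 20, seed = 3)
seqs <- build_sequences(rec, mcfg, days = 1:21)
model <- cgp_train(seqs, mcfg)
model
#> <cgp_model> LSTM(16) + dense(32) -> 100-point grid; final loss 0.638
```

Held-out next-step RMSE on days 22–28 is ~5–6 mg/dL, against ~11.7 for a
persistence (last-value) predictor and ~23 for predicting the training
mean; `cgp_ablation()` ranks nutrients as the dominant feature group,
ahead of time of day, heart rate and activity.

## Limitations

The synthetic cohort is a test harness, not a physiological simulation:
there is no insulin compartment, meals affect glucose through a fixed
kernel, and only logged meals influence the trace. Results on synthetic
cohorts demonstrate the correctness of the *pipeline*, not clinical
effect sizes. See the methods vignette (`vignettes/glucowear-methods.Rmd`)
for the modelling assumptions, parameter choices and study sizes.
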