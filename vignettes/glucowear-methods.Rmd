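---
title: "Methods: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific content of `glucowear`: the models
each module implements, the assumptions behind them, the parameters that
matter and why their defaults were chosen, and what passing the test
suite does and does not demonstrate.

## The problem

Digital metabolic-health programs pair a continuous glucose monitor
(CGM, sampling interstitial glucose every 15 minutes), a heart-rate
wearable, and an app in which participants log meals, activity and body
weight. Analyzing such programs raises recurring methodological
problems: wearable streams have coverage gaps; self-logged diet and
activity data carry logging bias that decays over the program; outcomes
are baseline-versus-end paired comparisons over subsets selected by
inclusion rules; and the personalization layer (glucose forecasting,
food recommendation) needs its own validation. Real program cohorts are
usually proprietary, so `glucowear` ships a synthetic-cohort generator
with known ground truth and validates every analysis stage against it.

## Synthetic cohort generator

A participant's glucose trace is

\[
g(t) = b_c + A\cos\!\left(\frac{2\pi (t_{\mathrm{day}} - 420)}{1440}\right)
 + \sum_{m} P_m\, h(t - t_m) + \varepsilon(t),
\]

with basal level \(b_c\) by glycemic category (defaults 90, 105 and 140
mg/dL for healthy, prediabetes and T2D), a circadian term of amplitude
\(A \le 10\) mg/dL peaking near 07:00 (time of day is a real but
secondary driver, which is what the ablation analysis should recover),
Gaussian sensor noise (default SD 5 mg/dL), and one kernel response per
*logged* meal. The kernel is gamma-like with unit peak at the rise time,

\[
h(t) = (t/\tau_r)^{\tau_r/\tau_d}\, e^{(\tau_r - t)/\tau_d},
\qquad
P_m = a \cdot \mathrm{carb}_m \cdot \max(0,\, 1 - f \cdot \mathrm{fiber}_m),
\]

with defaults \(\tau_r = \tau_d = 30\) min, amplitude \(a = 1.2\)
mg/dL per carbohydrate gram and fiber attenuation \(f = 0.02\) per gram.
With these defaults a typical 70 g-carb meal peaks ~75 mg/dL above
basal 30 minutes after eating and returns below 1 mg/dL within 4 hours.
Carbohydrates are deliberately the dominant driver; heart rate has *no*
causal effect on glucose, which gives ablation analysis a known correct
answer (nutrients ≫ time of day > heart rate ≈ activity ≈ 0).

Key structural choices:

* **Meals exist if and only if they are logged.** Each day offers three
  main meals and an occasional snack; each is logged with probability
  equal to the day's adherence. This makes logging adherence part of
  the physiology-as-observed, which is the simplest structure that
  exercises every logging-bias correction downstream. A consequence is
  that decaying adherence is itself a time trend in glucose-level
  metrics; the null-calibration study therefore uses constant adherence
  (see below).
* **Adherence** interpolates linearly from 81% (day 1) to 43% (day 28) —
  the shape of logging decay observed in program cohorts — but is
  participant-correlated: a fraction of participants (default 45%) are
  "engaged" loggers whose adherence never drops below 0.98. Without
  this mixture no participant could satisfy the log-every-day inclusion
  rule, whereas roughly half of a real self-selected cohort does.
* **Meal composition is independent of meal size.** Per-meal nutrient
  amounts are (mean-one lognormal fluctuations) × (meal-size factor) ×
  (population means: 70 g carbohydrate, 30 g protein, 25 g fat, 6 g
  fiber, 700 logged kcal per unit size). Because size cancels in
  nutrient-to-calorie ratios, the pooled carbohydrate-calorie share has
  the closed form \(4C/K\) at baseline and
  \(4C(1-\delta)/(K - 4\delta C)\) under a carbohydrate cut \(\delta\)
  (`expected_carb_ratio_change()`), which serves as the analytic oracle
  in effect-recovery tests. The ~2,200 kcal fully-logged day also keeps
  the 1600-kcal good-day rule from selecting on composition.
* **Signal loss** is placed as contiguous 1–8 h gaps (sensor dropouts)
  until the target fraction of slots (default 10%) is reached, the last
  gap being trimmed so the realized fraction is exact.
* **The injected effect** reduces carbohydrate (and proportionally sugar
  and calories) of meals from day 15 onward and lengthens exercise
  bouts. Body weight drifts at one pound per 3,500 kcal of cumulative
  deficit attributable to the effect (carbohydrate-cut calories scaled
  by 1/adherence to account for unlogged meals, plus extra exercise
  burn), so weight is flat under a null generator.

The generator emulates the statistical structure the analyses assume; it
is *not* a physiological simulation. There is no insulin compartment, no
glycemic differences between categories beyond the basal shift, no
inter-meal interaction, and heart rate does not influence glucose.
Passing tests on these cohorts demonstrates that the pipeline measures
what it claims to measure, not that real interventions have these effect
sizes.

## Inclusion rules and analysis windows

The quality-control module encodes the inclusion rules as inclusive
(≥) thresholds: 70% CGM coverage on at least half the days of each QC
window; at least two logging events on every day of the first 7 and last
14 days; at least one weight in days 1–7 and one in days 15–28; 20 h/day
heart-rate capture. A *good logging day* for dietary analysis has ≥2
logs, all within a 16-h window with a first-to-last span of ≥4 h (the
adopted reading of "spread throughout waking hours"), and ≥1600 kcal
logged. Resting heart rate is taken as the 5th percentile of per-minute
HR; participants above 110 bpm are excluded from HR-based activity
measures only.

The source methodology states the baseline QC window inconsistently
(days 3–7 in one place, days 1–5 excluding day 1 in another); the
package adopts days 2–7, aligned with the glycemic baseline window, and
exposes both bounds in `qc_thresholds()`. Analysis windows are days 2–7
(baseline; day 1 is excluded because first-day CGM readings are known to
be less accurate) versus days 14–28 (end); activity and food-logging
variables use days 1–5 as their baseline.

## Glycemic metrics

Time in range uses 70–180 mg/dL for T2D and 70–140 mg/dL otherwise,
inclusive at both bounds, over non-missing samples. GMI uses the
consensus linear calibration \(3.31 + 0.02392 \cdot \bar g\); the
coefficients are arguments so an alternative calibration can be swapped
in. Glycemic variability is the sample (n−1) coefficient of variation
over the whole window, not averaged per day — the simplest reading of
"coefficient of variation".

An excursion *event* is a maximal run of at least 2 consecutive
non-missing beyond-threshold samples; runs whose separating interval is
shorter than 30 minutes are merged first, so a single transient dip does
not split one excursion into two. Both knobs are arguments of
`count_events()`. Event rates — and only event rates — are adjusted for
lost time by dividing by `window days × (1 − missing fraction)`;
mean-based metrics need no such adjustment because missing samples
simply drop from their denominators. Note that the threshold-nesting
property (events >250 ≤ events >180 ≤ events >140) is a property of
excursion-shaped traces, not of arbitrary series: on white noise,
merging can make the lower-threshold count smaller. The tests check it
on generated records.

Subgroups are defined on baseline values only (all, TIR < 90%,
TIR < 70%, GMI > 6%, GMI > 7%), and empty subgroups are reported as
absent rows rather than zeros.

## Behavior metrics

Nutrient summaries pool over good logging days: macronutrient calories
are grams × 4 (carbohydrate, sugar, protein) or × 9 (fat, saturated
fat), divided by the *logged* total calories (the two can disagree, as
they do in real food logs); fiber is reported as grams per total kcal.
Duplicating a good day's logs leaves every ratio unchanged — the whole
point of ratio-based diet metrics is logging-frequency invariance, and
that invariance is a test.

Adjusted activity divides raw logged minutes/day by the ratio of the
window's app-interaction rate (all log events of any type) to the
baseline window's rate, so behavior-unchanged participants are
untouched and under-loggers are scaled up. No formula being given for
this adjustment in the source methodology, the ratio normalization was
chosen because it preserves the identity case exactly.

Weight change compares the first measurement in days 1–7 with the last
in days 15–28, with lower-inclusive baseline-weight strata (a 250.0 lb
participant belongs to 250–300). Twelve-week columns appear only when
the program actually contains the extended window (days 70–84).

## The recurrent glucose predictor

Inputs are 15-minute feature frames: glucose, heart rate (step mean),
exercise minutes in the step, time of day as a (sin, cos) pair, and the
nutrient totals of foods logged in the step (7 values). Features are
standardized with fixed, data-independent centers and scales so that
models are portable across records. A *complete day* has at least 12 h
of both CGM and HR capture and at least two logged meals; sequences of
`sequence_length` frames (default 16, i.e. 4 h) slide within complete
days with the next step's glucose as target, and a participant needs 5
complete days by default.

The network is a single LSTM layer (default 16 units) followed by a
dense tanh layer (default 32) and a categorical output head: a softmax
over a fixed grid of 100 candidate glucose values, uniform on 40–400
mg/dL. The point estimate is the distribution expectation and the
10/25/75/90 percentile bands come from the discrete CDF. Training
minimizes the negative log-likelihood of the observed next step's
nearest grid cell with Adam (default learning rate 0.02, batch 32, 15
epochs); the forget-gate bias is initialized at +1. A categorical head
was chosen over a scalar sigmoid output because only a distribution
over candidate values is consistent with likelihood training and
percentile bands; the grid spacing (~3.6 mg/dL) bounds the
quantization error of the expectation well below sensor noise.

Feedback of the model's own predictions uses scheduled sampling: each
epoch, one batched pass computes one-step predictions for every
position, and each frame's glucose input is replaced by the model's
prediction with a probability that ramps linearly from 0 to 1 over the
epochs (stop-gradient through the fed-back value; mixing is done per
day so overlapping windows agree). This is an approximation of
on-the-fly decoder sampling, chosen because it preserves full batch
parallelism; it trains the model to tolerate its own errors, which is
what the autoregressive uses (post-meal forecasting, virtual CGM)
require.

Post-meal forecasting places the hypothetical meal's nutrients in the
final context frame and rolls 8 steps (2 h) autoregressively. The
virtual-CGM rollout does the same over a full day given only food and
heart-rate inputs, seeded by a context at a known glucose level.
Evaluation reports point-by-point RMSE, the minimum RMSE over lags up to
±2 steps (±30 min; lag 0 included, so the shifted RMSE can never exceed
the plain one), peak RMSE over 2-h windows, MAPE, and linear
correlation.

Ablation retrains with feature groups zeroed (nutrients, time of day,
heart rate, activity; glucose history is always kept): forward mode
greedily removes the group whose removal degrades held-out RMSE most,
reverse mode starts from glucose-history-only and greedily adds. On
kernel-generated data the correct answer is known by construction, and
the tests require nutrients to rank first in ≥90% of seeds. Per-user
tuning is a seeded random search over LSTM size, learning rate and
sequence length on a per-user validation split, returning the base
configuration unless a candidate strictly improves validation NLL —
a deliberately simple stand-in for meta-learned hyperparameter
optimization, which cannot be reproduced from its published
description.

One known limitation: the percentile bands reflect one-step predictive
uncertainty only. Over a long autoregressive rollout errors accumulate
faster than the bands widen, so empirical 10–90 band coverage on noisy
data is typically 60–90% rather than the nominal 80%; on noiseless data
the distribution is nearly degenerate and coverage is not meaningful.

## Food recommendation

Similarity is the cosine of per-100-kcal nutrient density vectors
(six nutrients; energy density cancels so a double serving is identical
to a single one) blended 80/20 with a category-match indicator.
Healthiness is `2 × fiber − 1 × (carb − fiber)` per 100 kcal — an
invented but documented formula using exactly the stated ingredients
(carbohydrate and fiber composition); both weights are arguments. The
four stages run in a fixed order — similarity ≥ τ, blacklist removal,
healthiness ranking (ties broken by similarity, then id), cleanup
(missing nutrients or not strictly healthier than the query) — and the
test suite checks the composition against a brute-force enumeration of
the whole database.

Spiking foods are ranked by mean incremental AUC over the 2-h post-meal
window (trapezoidal, baseline = median of readings in the 15 min before
the log); meals falling in CGM gaps contribute nothing and foods with
fewer than two usable exposures are flagged low-confidence. The
intervention plan uses Mifflin-St Jeor × activity factor for
maintenance calories with a 500 kcal/day deficit floored at 1,200
kcal/day, fiber goals of 21–25 g/day (female) and 30–35 g/day (male), a
post-meal activity suggestion, and a 16-h fasting target with the
achieved fast measured as the mean longest daily meal-free interval.

## Statistics and study sizes

Baseline-versus-end comparisons use the classic paired t-test on
per-participant deltas (two-sided), with Shapiro–Wilk on the deltas at
α = 0.05 reported as a flag only and a log-transformation hook that is
off by default. p-values are uncorrected to match how such program
outcomes are conventionally reported; a Benjamini–Hochberg switch is
available and documented as a deviation. Zero-variance deltas return an
explicit degenerate flag rather than a statistic.

The simulation studies run at sizes chosen to give stable Monte-Carlo
estimates at interactive timescales on one CPU:

* *Effect recovery* (`effect_recovery_study()`): 20 cohorts of n = 200
  with a 30% end-window carbohydrate cut. The carb-ratio recovery is
  measured over the treated days (15–28) and over participants passing
  the meal-logging rule, mirroring how dietary outcomes are restricted
  to consistent loggers; both choices remove finite-sample selection
  biases that would otherwise displace the estimate from the closed
  form (sporadic loggers' rare qualifying days are selected on day
  size).
* *Type-I calibration* (`type1_calibration_study()`): 500 replicate
  cohorts of n = 12 from the null generator — zero effect *and*
  constant adherence, since with logged-meals-drive-glucose a decaying
  adherence is itself a trend and the null would be false.
* *Predictor sanity*: one noiseless fully-adherent participant, 21
  training days / 7 held-out days, 16 LSTM units, 20 epochs; the model
  must beat persistence and mean baselines and land under 10 mg/dL
  held-out RMSE (the grid-quantization floor is ~1 mg/dL).
* *Ablation ordering*: 10 seeds, 12-day records, 12 units, 10 epochs;
  nutrients must rank first in at least 9.

`scripts/acceptance.R --seed S --out results.json` reruns all of the
above from scratch and writes the headline numbers as JSON; the seed
drives every source of randomness.

## Known limitations

* The generator's simplifications listed above; in particular, all
  glycemic categories share the same meal response, so category
  differences in recovered deltas are driven by basal levels and the
  T2D target range only.
* Event definitions ("≥2 consecutive samples", "<30-min merge") are
  configurable conventions; published event rates rarely state theirs,
  so absolute event rates are comparable only within a convention.
* The predictor is desk-scale by design. It demonstrates architecture
  and training correctness on kernel data; no claim is made about
  performance on real CGM traces, which have physiology the generator
  does not emulate.
* Rollout percentile bands are mildly overconfident (see above).
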