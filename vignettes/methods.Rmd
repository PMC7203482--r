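---
title: "Predicting affective learning states and outcomes from wearable sensors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting affective learning states and outcomes from wearable sensors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a one-hour self-regulated learning session, a participant ("proband",
the conventional term in this literature) wears two consumer-grade devices: a
five-electrode EEG headset that reports precomputed band power, and a
wristband sampling galvanic skin resistance (GSR, the reciprocal of skin
conductance) at 5 Hz. Every 270 s a vibration alarm prompts a parsimonious
in-task questionnaire — five bipolar sliders (interest, energy, valence,
focus, tension) on a \[-4000, 4000\] range — for 13 embedded experience
samples per session; answers must arrive within 60 s to count as valid. After
the session, the proband completes outcome questionnaires: six
self-determination regulation scales and six mood/motivation scales, each
scored as the mean of its ordinal items.

The scientific question is whether the sensor streams predict (a) the 13
in-task affective self-reports (process measures) and (b) the post-session
outcome scales, better than a sensor-free *mean-of-others* baseline. This
package implements that analysis end to end and, because the underlying human
dataset is not publicly available, ships a synthetic-cohort generator with
known ground truth so every stage is testable and planted effects are
recoverable.

## Sensor preprocessing

The headset does not expose raw EEG by default; it reports band power for
theta (4–8 Hz), alpha (8–12), lower beta (12–16), upper beta (16–25) and
gamma (25–45) at each of AF3, AF4, T7, T8 and Pz. `compute_band_power()`
emulates this on-device step for raw input: a 2 s periodic Hann window slides
over the 128 Hz signal, and per-band power is the sum of squared FFT
magnitudes over the positive-frequency bins whose frequency falls in the
half-open band interval (0.5 Hz resolution; the shared 8 Hz bin belongs to
alpha, not theta). Each frame is stamped with the window's end time.

Two numerical conventions are deliberate. First, the output hop is 16 samples,
giving the 8 Hz frame rate at which the device documentation says data are
returned; the vendor text also mentions a 125-sample step, which would give
roughly 1 Hz and contradict the 8 Hz rate, so 8 Hz is the default and the
step is overridable in `spectral_config()`. Second, power is a *sum* (not
mean) of squared magnitudes and no calibration constant is applied: every
downstream feature is compared within-pipeline, so a positive scale factor is
immaterial. Whether the real device reports sums or means, and in what units,
is undocumented; it is a config choice here.

## Masking and segmentation

While answering the questionnaire the proband is not learning, so sensor
samples inside each response window `[alarm, alarm + duration)` are removed
(`mask_response_windows()`). With the design's mean response time of 16.36 s,
13 windows mask about 6% of a 3600 s session. Late answers (over the 60 s
limit) are invalid as labels but still mask data up to the limit. All
intervals in the package are half-open `[start, end)`, so boundary samples
are never double-counted, and masking commutes with segmentation (this is
property-tested).

Process-level features use the 270 s preceding each alarm
(`segment_preceding()`, segments anchored at nominal alarm times); outcome
features use the masked whole session (`whole_session()`, index 0). Each
segment records its *coverage*, the retained share of its nominal sample
count; coverage below 0.5 is flagged. Flagged rows are retained by default
and excludable via `cohort_features(drop_flagged = TRUE)` — the choice is
exposed because the right handling of sparse segments is genuinely open.

## Features

Seven summary statistics per stream: mean, median, standard deviation
(sample, n−1 — the conventional choice), max, min, max−min, and *tendency*,
the median of the first 30 s minus the median of the last 30 s of the
segment's nominal span. The sign convention is the literal first-minus-last
reading; only the sign of learned weights depends on it, and it is stated
here prominently for that reason. Tendency is undefined (NA) when either 30 s
end-window holds no samples, e.g. when a long response mask swallows the
segment head; missing features are flagged, never dropped, and the CV drivers
impute them with training-column means frozen for prediction.

EEG streams beyond the 25 site-band series: BLA (`beta_low / alpha` per
site), the engagement index (`(beta_low + beta_high) / (theta + alpha)` per
site — the device has no unified beta band, so the numerator is the sum of
its two beta bands, the standard engagement numerator), and laterality
differences per band (temporal `T7 − T8`, anterior-frontal `AF3 − AF4`).
Ratio denominators are floored at 1e−12 and floor events are counted on the
returned series; the alternative (dropping the sample) would silently shift
the time base. That yields 45 streams × 7 statistics = 315 EEG features and
7 `GSR_*` EDA features, with names that parse back bijectively into
(stream, statistic).

## Models and evaluation

`fit_ridge()` solves the l2-penalized least-squares problem in closed form
(primal or dual normal equations, whichever is smaller) with an unpenalized
intercept. Features are standardized on training rows only and the statistics
frozen into the fit — predictions are invariant to affine rescaling of raw
features, and no test-row information leaks into the scaling. Gradient
boosting wraps XGBoost, single-threaded and seeded, so the same seed gives
bit-identical models; its per-feature gain serves as the importance weight.

Hyperparameters are tuned per training set by seeded random search (default
budget 50) over a documented space — ridge: log10 lambda in \[−4, 6\];
boosting: depth 2–8, learning rate 0.01–0.3, 50–500 rounds, subsample
0.5–1 — scored by threefold CV grouped by proband, so no proband ever sits on
both sides of an inner split. Recursive feature elimination
(`rfecv()`, off by default since the original analysis does not say when it
was active) drops the lowest-weight 10% per iteration and keeps the subset
with the best CV RMSE; score ties within a relative tolerance go to the
smaller subset, with name-order tie-breaking in the elimination ranking.

Evaluation mirrors the study design. Outcome scales use leave-one-out CV
(one row per proband); process scales use leave-one-proband-out CV (all 13
of a proband's samples held out together, inner tuning folds also grouped).
The baselines are sensor-free means of the other probands' labels: per-value
for LOO, grand-mean-of-others for LOPO. Two algebraic facts about the LOO
baseline are worth knowing when reading result tables: its label-prediction
correlation is exactly −1 for any non-constant label vector (the prediction
is a strictly decreasing affine function of the held-out label), and its RMSE
is `n/(n−1)` times the population SD of the labels. Both are property-tested.

Metrics are RMSE, MAE and LPC (Pearson r between predictions and labels),
computed on the pooled prediction vector for LOO and averaged per proband for
LOPO (the pooled LPC variant is also reported, since "averaging over all
probands" admits both readings). Model and baseline are compared by a
*paired* two-sided Student's t-test on per-fold absolute errors, with paired
effect size `d = mean(diff)/sd(diff)`; the pairing unit is the held-out fold.
The original tables mark methods with `+`/`*` without defining them; here `+`
means the method's error is below the baseline's and `*` means p < 0.05, and
`significant_improvement()` requires both. Missing process labels skip their
fold; zero-variance error differences flag the comparison rather than
producing spurious statistics. Scale reliability is Cronbach's alpha,
`k/(k−1) (1 − Σ var_j / var_total)`.

## The synthetic cohort

The generator's defaults are the study conditions: 3600 s sessions, 270 s
alarms (13 samples), response times truncated-normal(16.36, 7.36) on
(0, 60\], band power at 8 Hz, GSR at 5 Hz, sliders on \[-4000, 4000\], and
12 outcome scales with the study's reported reliabilities (0.37–0.90, 8 items
each). Where the study reports no value, the defaults are fixed once at
field-plausible levels: band-power baselines decreasing with frequency
(40/30/20/15/10 device units), lognormal multiplicative sensor noise
(sdlog 0.4), a latent affect state following a discrete-time mean-reverting
(AR(1)) process at 1 Hz with a 120 s relaxation time and unit stationary SD
(the simplest process with the slow drift experience sampling assumes),
upsampled linearly to sensor rates, slider loadings of roughly 1000–1500
slider units per state SD with 900 units of noise (tension loading
negatively), and a 300 kOhm baseline resistance with a −0.2 log drift over
the session and a negative state coupling (arousal lowers resistance).
Band-power noise is lognormal because power is positive and right-skewed;
slider clipping to ±4000 is applied after noise, matching the bounded
response scale.

Each proband carries six traits: one activation trait per electrode site
(multiplying that site's log band power across all bands) and a general
affect trait that shifts the latent state's level and loads on every outcome
factor. Outcome items come from a one-factor model per scale; the inter-item
correlation implied by the target alpha is pre-inflated by the analytic
rounding-attenuation factor `(s² + 1/12)/s²` so that alpha measured on the
rounded 5-point items still hits the target (verified at n = 500 within
0.05).

`plant_t7_effect(cfg, strength)` adds a negative loading of the T7 activation
trait on the `intrinsic_motivation` outcome factor, mirroring the kind of
left-temporal effect such a study can detect, while leaving all other sites
untouched; at strength 0 the cohort is bit-identical to the unplanted one.
"T7-derived" in the recovery checks counts T7 band-power features, T7 ratio
indices and the temporal laterality index (T7 − T8), matching the mix of
correlates such an effect produces.

What the generator does *not* emulate: volume conduction and electrode
cross-talk, artifacts (blinks, motion, electrode pops), vendor filtering,
phasic skin-conductance responses (only tonic drift plus state coupling),
non-stationary learning phases, and any nonlinear feature-label structure.
Passing tests therefore show that the pipeline recovers effects *of the
assumed form* at realistic sizes and noise levels — not that the original
study's conclusions replicate on real signals.

## Problem sizes and calibration

The planted-effect check uses 60-proband cohorts (the scale of the original
EEG sample) at strength 0.8, with significance assessed on a fixed-seed
cohort and T7 dominance of the top-10 correlation list taken as the median
over 10 seeds. The null calibration runs the identical pipeline on 20
cohorts of 30 probands with strength 0 and requires significant improvement
over baseline in at most 10% of runs; 30 probands keeps the 20-run
calibration tractable while staying a realistic study size. Unit tests use
smaller cohorts (1–8 probands, often shortened sessions) since they exercise
contracts, not statistical power.

## Known limitations

- Process-level prediction power is limited by design: slider labels derive
  from the latent state at alarm times with substantial noise, and shared
  time trends are unpredictable by construction under the LOPO baseline.
- The dual-form ridge at lambda near machine precision is ill-conditioned
  when features duplicate; the RFE tie tolerance exists for exactly that
  regime.
- Cronbach's alpha targets are calibrated for the rounding attenuation but
  not for ceiling/floor clipping, which is negligible at the default item
  scale (mean 2, SD 0.9 on 0–4) but not for extreme configs.
- The t-test on per-fold absolute errors treats folds as independent;
  LOO folds share training data, a standard but real approximation.
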