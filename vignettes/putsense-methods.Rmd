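---
title: "Detecting rare perceived-unfair-treatment days from passive sensing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare perceived-unfair-treatment days from passive sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(putsense)
```

## The problem

Perceived unfair treatment (PUT) is a self-reported, binary, day-level
outcome: on roughly 1 day in 20 a student reports having been treated
unjustly based on group characteristics. The question `putsense`
operationalizes is whether such days can be detected *after the fact* from
passively sensed smartphone and wearable behavior alone — location traces,
activity recognition, screen events, calls, Bluetooth/Wi-Fi scans, battery
samples, per-minute steps and sleep episodes — without asking the student
anything. The positive class is rare (a mean per-user reporting rate of
4.66%), the labels come from ecological momentary assessment (EMA) prompts,
and every sensing stream is intermittently missing, so the pipeline is as
much about honest rare-event evaluation as about any single model.

Because raw student sensing data are private, the package is built around a
seeded synthetic cohort generator whose statistical structure matches what
the analysis assumes, so every downstream stage is testable without any
download. The generator is first-class, tested code, not a fixture.

## The unit of analysis and the feature catalog

The unit is the *person-day*. Events are aggregated over five within-day
epochs — night [00:00, 06:00), morning [06:00, 12:00), afternoon
[12:00, 18:00), evening [18:00, 24:00), and the whole day — using half-open
intervals in local time; interval events (screen bouts, dwell intervals,
stays) are clipped at epoch edges with pro-rated durations. The catalog
(`feature_catalog()`, 164 features) crosses each base statistic with its
applicable epochs and adds one sample-count feature per stream and epoch:

* **Location**: off-campus dwell time and share against a semantic campus
  map (boundary disc plus building/study/green zones), stay-point
  statistics (stays = fixes within 100 m sustained 10 min or more),
  log-variance of coordinates, and a circadian-movement statistic
  (least-squares spectral power of latitude/longitude in the 23.5–24.5 h
  band over a trailing 7-day buffer, reported under the night epoch).
  Per-fix dwell is the time to the next fix; the gap is counted in full
  while the on/off-campus classification is unchanged and capped at 15
  minutes at transitions and at the day end, where the crossing time is
  unknown.
* **Screen**: total on-time, unlock counts, first unlock time, shortest
  interaction (unlock-to-off) bout. Unmatched on/off events are dropped.
* **Steps**: totals plus run-length structure of the per-minute series —
  active bouts are maximal runs of minutes with at least 10 steps;
  `avg_steps_active_bout` is per-minute intensity averaged over bouts
  (a two-minute bout of 50 steps scores 25).
* **Calls / Bluetooth / Wi-Fi**: missed-call and call counts, call
  duration, scan counts, distinct access points. Count features are 0 (not
  missing) when a stream is present but empty.
* **Activity and the fused feature**: minutes labeled
  walking/running/cycling; *indoor mobility* fuses activity and location —
  walking minutes whose nearest fix (within 10 minutes) lies inside a
  campus building zone — and is missing unless both streams are present.
* **Sleep** (daily only): onset, duration, minute count. Onset is encoded
  as seconds since midnight of the onset calendar day (23:30 → 84,600;
  01:10 → 4,200). This published convention wraps at midnight, so a *later
  onset* does not shift the encoded value monotonically when onsets
  straddle midnight; the generator therefore calibrates the sleep shift on
  duration, and the onset encoding is exposed as-is with this caveat. (The
  original tabulated onset means, around 34,600 s ≈ 09:36, are hard to
  reconcile with a nightly onset under any midnight-anchored encoding;
  we treat the encoder as a replaceable convention.)

Missingness propagates structurally: an absent stream makes all its
features missing (sample count included); fused features require both
parents; presence flags ride along with every row.

## The synthetic cohort

Each participant gets a latent routine: a home anchor (on-campus dorm or
off-campus commute, 50/50), habitual sleep onset (23:45 ± 40 min,
constrained to 20:00–04:00) and duration (450 ± 35 min), mean daily steps,
screen propensity, and user-level components of each calibrated behavioral
quantity. A day is generated as a minute-state timeline (sleep → campus
blocks with building/study/green segments and walking transitions →
off-campus time at the end of the day), from which all nine streams are
emitted: 5-minute location fixes with 15 m jitter, ~75 s activity samples,
per-minute steps built from epoch totals via active bursts, screen bouts
summing to epoch targets, calls, Bluetooth/Wi-Fi scans, hourly battery, and
one nightly sleep episode that may cross midnight.

Per-user PUT rates are Beta-distributed with mean 0.0466 and concentration
5 — the mean and its across-user confidence band are externally
constrained; the concentration is our calibration choice (flagged in the
manifest) such that the central 95% range of per-user rates brackets
3.13%–6.19%. Day flags are Bernoulli within user.

On PUT days the *latent routine* is shifted — not the features — in the
directions the field reports: more time off campus, more evening steps and
evening physical activity, longer afternoon screen time, more evening
missed calls, fewer morning Bluetooth detections, more night-time activity
samples, less indoor mobility, later onset and shorter sleep. Shift
magnitudes are `SMD × population SD`, with the population SD derived
analytically from the generator's own variance components; a few shifts
carry fixed correction factors (measured once from a design pilot)
compensating attenuation from zero-truncation, count-dispersion growth and
schedule caps. The realized effect sizes on extracted features land within
±0.1 of the configured targets over 5,000+ simulated days — that is the
generator's calibration invariant, tested as such. A fast path
(`generate_feature_table()`) draws standardized features directly from a
per-user random-effects Gaussian model (`value = u + e`, ICC 0.5 by
default) with the same shifts and missingness, trading event realism for
speed; the two paths share one ground truth.

**Missingness.** Availability is reported per stream per day. Real
compliance is strongly correlated across streams (a dead phone loses all
seven phone streams at once); independent per-stream drops at the published
marginal rates would leave only ~10% of days with ≥7 streams, an order of
magnitude below the usable-day counts the study design implies. The
generator therefore uses a day-level compliance mixture: a day is compliant
with probability 0.705; on compliant days each stream is kept with
probability `rate / 0.705`, otherwise everything is absent. The per-stream
marginals match the configured rates exactly, and `compliance = 1` recovers
fully independent drops. Missingness is never outcome-dependent (MCAR).

**EMA schedule.** Twice-weekly prompts (Sundays and Wednesdays) reference
the *previous* day; two-week daily blocks reference the same day; prompts
are unanswered with probability 0.2 (a compliance choice mirroring the
observed response volume); answered prompts equal the ground truth, with
label noise available as an experiment knob but 0 by default — reporting
subjectivity is a scenario to study, not a baseline assumption.

**What the generator does not emulate:** within-day dropout, device-specific
payload quirks, multi-timezone travel, informative (outcome-dependent)
missingness, and EMA nonresponse bias. Passing recovery tests therefore
show that the *pipeline* recovers planted structure under realistic rarity,
effect sizes and missingness — not that real PUT days are detectable at
these accuracies.

## Dataset assembly

EMA answers resolve to labels yes-dominantly (any "yes" referencing a day
makes it positive; conflicts are resolved toward yes); unanswered days stay
unlabeled and may serve as sequence context but never as supervised
targets. The population track filters rows to ≥7 available streams. Two
sequence constructions feed the detector:

* **Intraday**: a 4 × F tensor per labeled day (night, morning, afternoon,
  evening rows of each epoch-resolved base statistic). Daily-only features
  are excluded with a warning.
* **Multiday**: an N × F tensor of daily features ending at the target day
  (N ∈ {3, 5, 7, 9}); calendar gaps become fully masked rows.

Sequences with more than 80% missing entries are dropped, multiday
sequences also when the target day exceeds 50% missingness. Masked entries
are stored as mask + sentinel, never imputed, because the loss is
mask-aware. The chronological split is per participant (the tabulated
per-user train/test means imply per-participant splitting; a pooled split
is available via `split_spec(pooled = TRUE)`): the earliest
`floor(0.9 n)` negatives train, everything else — all positives plus the
latest negatives — tests, and any multiday training window covering a
positive test day of the same participant is removed.

## The user-independent benchmark

Five classifier families (k-NN, logistic regression, RBF-SVM, random
forest, gradient-boosted trees) and three baselines (uniform: random
scores, coin-flip labels; stratified: random scores, labels at training
prevalence; demographic: the gradient-boosted family on static demographics
only) are compared under nested stratified group cross-validation: outer
K = 5 assigns whole participants to folds greedily balancing positive
counts (zero-positive participants balance fold sizes), inner K = 4 selects
hyperparameters and the imbalance strategy by mean AUC-PR — the metric that
stays informative at 3–5% prevalence. Median imputation is fit on training
folds only; the gradient-boosted family uses native missing-value handling
instead. SMOTE and SVM-SMOTE are implemented directly (synthetic minority
points are convex combinations of minority neighbors; the SVM variant seeds
them at minority support vectors) and only ever touch training folds.
Thresholded metrics use the training prevalence as cutoff. Five repeats of
the outer loop give 25 estimates per model; information-gain (Gain)
importances are averaged across outer folds, and the top-k features
(k ∈ {50, 100, 150}) feed the anomaly track. Hyperparameter grids are
deliberately small (trees 100–300, depth 3–8, k ∈ {5, 15, 35}, SVM cost
{0.1, 1}) and config-exposed, since no grids are externally prescribed.

## The user-dependent LSTM autoencoder

The detector is a sequence autoencoder: two stacked LSTM encoder layers
(widths 64, 32) compress the input to the final hidden state, which is
repeated T times and decoded by two stacked LSTM layers (32, 64) and a
time-distributed dense head. Training minimizes the *masked* mean squared
error — squared residuals averaged over observed positions only — with
Adam (learning rate 1e-3, batch 32, up to 100 epochs, early stopping with
patience 10 on a 10% slice of the training negatives), on negative days
only. The implementation is plain vectorized R: forward, backpropagation
through time and Adam are written out explicitly, and the gradients are
verified against central finite differences in the test suite. Masked
entries are zero-filled after standardization for the forward pass; the
loss mask prevents any gradient from unobserved positions.

Scaling statistics come from observed training entries only (constant
features get SD 1). By default each participant's sequences are *centred
on their own training mean* (a shrinkage estimate pulling 2
pseudo-observations toward the global mean) before global scaling. This
is not cosmetic: a pooled negatives-only model with purely global scaling
is structurally biased under between-user heterogeneity — participants
with many positive days contribute fewer training sequences (their
positives never train and the leakage rule removes more), the model
represents them worse, and their days score anomalous regardless of
label. In null cohorts (all effects zero) we measured AUROC 0.58–0.75
for globally scaled models, *worsening* with training, versus ~0.52–0.55
with shrinkage centring — a small residual positive bias remains (centre
estimates are noisier for sparsely represented users) but sits within the
chance band once averaged over cohorts. Per-user centring restores chance-level null scores
and makes any detected signal attributable to day-level deviations rather
than representation artifacts; `per_user_scaling = FALSE` reproduces the
global behavior. Scoring
follows the sequence mode: intraday sequences score by whole-sequence
masked error, multiday sequences by the error of the target (last) row
only. The anomaly threshold is the linear-interpolated (type 7) 75th
percentile of training reconstruction errors — conservative and
data-driven, with the estimator exposed because percentile conventions
differ. A sample with nothing observed in scope is unscoreable and is
skipped with a count. Experiments repeat over 10 random initializations
and report mean (SD) per metric, with uniform and stratified baselines
evaluated on the same test labels.

One design question deserves note: "user-dependent" could mean one model
per participant or one global model on within-user chronological history.
The pooled training counts (thousands of sequences against ~20–30 per
user) make per-user training implausible at this scale, so the default is
a single global model over all participants' early negatives, personalized
through the within-user chronological split and optional per-user scaling.

## Evaluation statistics

AUROC is the midrank Mann–Whitney statistic (ties count ½); AUC-PR is
average precision by step integration over distinct thresholds —
trapezoidal interpolation optimistically biases PR curves under imbalance,
so it is not used. Paired one-sided Wilcoxon signed-rank tests compare a
model against a baseline across the paired (repeat, fold) or run indices:
exact by sign-flip enumeration up to n = 14 (valid under ties), exact via
the signed-rank distribution up to n = 25 without ties, and a
tie-corrected normal approximation beyond. Benjamini–Hochberg controls the
false discovery rate across comparisons. Standardized mean differences use
the pooled-SD formula; relative improvements are reported in percent to
one decimal.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise the claims at
desk scale: the generator's calibration runs on 5,200 event-level
person-days; the recovery experiments use a 100-participant × 70-day
cohort at 4.66% prevalence with the default effect profile (detector
recall and F1 against the uniform baseline across 10 runs, paired
one-sided Wilcoxon), a zero-effect replicate for chance-level calibration
of every benchmark model over 25 estimates, and a sparse 5-feature
profile for importance-recovery across 10 seeds — sparse because a decile
of 164 features has 17 slots, so a dense 18-feature profile could never
fit it. Reduced epochs (15–30) and larger batches are used in these
experiments; the model defaults remain the full schedule. All randomness
flows from one root seed through named substreams (`derive_seed()`), so
every stage is independently reproducible.

One negative result is worth stating plainly: information-gain rank
recovery of *weak* planted effects is unreliable at this scale. With
roughly 300 positive days, a feature planted at SMD 0.33 realizes an
effect anywhere between ~0.20 and ~0.36 from cohort sampling alone, and
at the low end its Gain rank falls among the unplanted features —
regardless of fold averaging or booster regularization. Features at SMD
0.37 and above recover essentially always. Importance rankings of
small-effect features at rare-event sample sizes should be read with
corresponding caution.

Known limitations: the event generator realizes count-valued streams from
calibrated epoch-level targets rather than a fully coherent behavioral
simulation, so cross-feature correlations are weaker than in real data;
the compliance mixture is a single-parameter approximation to real
missingness structure; the sleep-onset encoding question above; and
synthetic demographics exist solely to exercise the demographic baseline,
carrying no signal by construction.
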