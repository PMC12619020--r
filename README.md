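# putsense

Detecting rare self-reported *perceived unfair treatment* (PUT) days from
passively sensed smartphone and wearable behavior.

## The problem

On roughly 1 day in 20, a college student reports — via a brief ecological
momentary assessment (EMA) survey — having been treated unjustly based on
group characteristics. `putsense` asks whether such days can be detected
*after the fact* from passive sensing alone: GPS fixes, activity
recognition, screen events, call logs, Bluetooth/Wi-Fi scans, battery
samples, per-minute step counts and sleep episodes. It is written for
researchers in digital phenotyping and mobile health who need a complete,
testable rare-event-detection pipeline: because raw student sensing data
are private, the package ships a seeded synthetic cohort generator whose
statistical structure (rare positives, small-to-moderate behavioral
shifts, realistic stream missingness, an EMA labeling schedule) stands in
for the real data end to end.

## What it computes

The pipeline has two detection tracks over person-day feature vectors
(164 features: per-epoch behavioral statistics plus per-stream sample
counts, epochs = night/morning/afternoon/evening/all-day):

1. **User-independent classification.** Five classifier families (k-NN,
   logistic regression, SVM, random forest, gradient-boosted trees) and
   three baselines under *nested stratified group K-fold cross-validation*
   (outer K=5, inner K=4; participants never straddle a train/test
   boundary; the inner loop selects hyperparameters and the imbalance
   strategy — class weights, SMOTE, SVM-SMOTE — by AUC-PR). Decisions use
   the prevalence threshold τ = n₊/n; 5 repeats give 25 estimates per
   model. Information-gain importances averaged over folds rank features.

2. **User-dependent anomaly detection.** A masked LSTM autoencoder
   (2 stacked LSTM encoder layers → repeated code → 2 stacked LSTM decoder
   layers → dense head, implemented from scratch in vectorized base R with
   finite-difference-verified gradients) is trained only on each
   participant's chronologically early negative days, minimizing the
   masked MSE

   L(x, x̂) = Σ_{(t,f) observed} (x_{tf} − x̂_{tf})² / #observed,

   and scores a day by its reconstruction error (whole 4-epoch sequence
   intraday; target-day-only error for N-day multiday sequences,
   N ∈ {3,5,7,9}). Days with error above θ = the 75th percentile of
   training errors are flagged. Splits are chronological 90:10 per
   participant, positives never train, training windows covering positive
   test days are excluded, and sequences with >80% missing entries (or
   >50% on the target day) are dropped.

Evaluation uses AUROC (midrank), AUC-PR (average precision), precision /
recall / F1 at the stated thresholds, paired one-sided Wilcoxon
signed-rank tests with Benjamini–Hochberg correction, and pooled-SD
standardized mean differences (SMD) for effect sizes.

## A worked example

Simulate a 100-participant, 70-day cohort, run the classification
benchmark, feed the top-50 features into the multiday detector, and
compare against naive baselines (under 3 minutes on one CPU at these
reduced training schedules):

```r
library(putsense)
cfg <- pipeline_config(
  cohort = cohort_config(n_participants = 100, n_days = 70, seed = 7),
  ae = ae_config("multiday", n_features = 50, window = 7, epochs = 30,
                 batch_size = 128, lr = 3e-3, patience = 8, n_runs = 3),
  top_k = 50,
  model_specs = list(
    gradient_boosted_trees = model_spec("gradient_boosted_trees",
                                        grid = list(nrounds = 150,
                                                    max_depth = 3)),
    baseline_uniform = model_spec("baseline_uniform", imbalance = "none"),
    baseline_stratified = model_spec("baseline_stratified",
                                     imbalance = "none")),
  cv = list(outer_k = 5, inner_k = 3, repeats = 2, tune = FALSE),
  seed = 42)
res <- run_pipeline(cfg)
print(res$anomaly)
```

```
<put_anomaly_experiment> mode=multiday k=50 N=7 runs=3
                   auroc          aupr     precision        recall
model      0.550 (0.008) 0.320 (0.005) 0.324 (0.007) 0.730 (0.061)
uniform    0.499 (0.021) 0.296 (0.013) 0.296 (0.031) 0.524 (0.072)
stratified 0.493 (0.029) 0.289 (0.024) 0.144 (0.053) 0.020 (0.007)
                      f1
model      0.449 (0.017)
uniform    0.378 (0.044)
stratified 0.035 (0.012)
```

Reading the table: each cell is mean (SD) across the 3 randomized runs on
the held-out test set (all positive days plus the latest 10% of negative
days). The detector recalls 73% of injected PUT days — against 52% for a
coin-flip baseline — at slightly better precision, so F1 rises from 0.378
to 0.449; AUROC 0.550 shows the reconstruction error ranks PUT days
higher than chance. The feature ranking that fed the detector is in
`res$importances` (night activity counts, off-campus share and evening
sedentary time lead, matching the injected behavioral shifts), and
`res$comparisons` holds the paired one-sided Wilcoxon p-values (with only
3 runs the smallest attainable p is 0.125; the acceptance experiments use
10 runs). `print(res$benchmark)` shows the user-independent track, whose
per-fold AUROC is noisy at ~45 labeled positives — expected under this
rarity.

`render_report(res, "report/")` writes the availability, metric,
comparison and importance tables as CSV plus a Markdown summary.

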