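# acrboost

Recognising aggressive drivers from roadside vehicle-trajectory data is an
imbalanced classification problem: the dangerous minority a safety analyst
cares about is a small fraction of the driver population. `acrboost` is an R
package for the full analysis chain on car-following trajectories sampled at
0.1 s:

1. **Average Crash Risk (ACR)** — a collision-surrogate statistic per driver.
   For a follower with speed *v_f*, leader speed *v_l*, bumper gap *d* and
   reaction time *τ*, the stopping-distance margin is

   ```
   DSS(t) = (v_l²(t) − v_f²(t)) / (2 μ g) + d(t) − τ v_f(t)
   ```

   with friction μ = 0.7, g = 9.8 m/s², and τ = 1.5 s while accelerating,
   0.7 s while decelerating or idling. Crash risk is the time deficit
   `CR(t) = |DSS(t)| / v_f(t)` when DSS ≤ 0 (else 0), and
   `ACR = (1/T) Σ CR(t) Δt` — the time-average crash risk of the episode,
   in seconds. Negative DSS means the follower cannot stop in time if the
   leader brakes hard.

2. **Aggressiveness labeling** by anomaly thresholds on the per-driver ACR:
   exact 1-D two-cluster k-means (sorted-split enumeration, deterministic),
   the interquartile-range outlier rule `Q3 + 1.5·IQR`, or a percentile
   (default 94th). Labels are `aggressive` iff ACR strictly exceeds the
   threshold. Leader–follower ACR correlation checks that a driver's risk is
   their own trait, not inherited traffic state.

3. **Spectral features**: each episode's gap, speed and acceleration series
   are reduced to the amplitudes of their first 15 DFT coefficients
   (`|DFT_k|/N`, k = 0..14), giving fixed-length feature vectors for
   variable-length episodes.

4. **Imbalanced-class boosting**, written from scratch on AdaBoost.M1 with
   depth-limited CART weak learners: cost-sensitive AdaBoost, SMOTEBoost,
   RUSBoost and CUSBoost (fresh SMOTE / random / cluster-proportional
   rebalancing inside every boosting round), plus one-shot
   resample-then-boost baselines and a gradient-boosted-tree (xgboost)
   baseline — the nine-algorithm benchmark.

5. **Evaluation** by precision, recall, F1 and the area under the
   precision–recall curve (step-wise average precision), under repeated
   stratified 5×5-fold cross-validation with optional grid search confined
   to training folds.

A seeded Intelligent-Driver-Model platoon simulator with a known aggressive
minority (short time gaps, NGSIM-like measurement noise) makes every stage
testable without external data; an NGSIM-schema CSV reader ingests real
trajectory tables (`us_customary` feet are converted on read).

## Worked example

```r
library(acrboost)

cfg     <- sim_config(n_drivers = 100, aggressive_fraction = 0.15,
                      duration = 60, seed = 42)
platoon <- simulate_platoon(sample_population(cfg), cfg)
acr     <- acr_table(platoon$episodes)

thr <- kmeans_threshold(acr$acr)
#> <acr_threshold> kmeans: 0.1759 s
labels <- label_drivers(acr, thr, truth = platoon$truth)
#> <labeled_drivers> 100 drivers, 15 aggressive (15.0%, imbalance 5.7:1)
#>   at ACR > 0.1759 s

fm <- build_feature_matrix(platoon$episodes, labels, channels = "gap")
repeated_stratified_cv(fm, model_spec("cusboost", rounds = 30), seed = 7)
#> <eval_report> cusboost, 5x5-fold CV (seed 7)
#>   precision 1.000  recall 1.000  F1 1.000  AUPRC 1.000
```

The k-means threshold lands at 0.18 s of average crash risk and flags 15% of
drivers; gap-spectrum features then separate them essentially perfectly.
Re-running with `channels = c("speed", "acceleration")` drops CUSBoost's
AUPRC to 0.217 — the gap between vehicles, not the follower's kinematics, is
the informative channel. The leader–follower ACR correlation on the same
platoon is −0.13 over 99 pairs, consistent with aggressiveness being an
individual trait.

The five-dataset benchmark (channel sets × threshold rules, nine algorithms)
runs end to end with:

```r
report <- run_experiment(experiment_config(seed = 1))
report$tables$dataset2        # algorithm × precision/recall/F1/AUPRC
```

or from a shell via `inst/scripts/acr-pipeline.R --config cfg.yaml`.

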