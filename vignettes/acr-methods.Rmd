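---
title: "Average Crash Risk and imbalanced-class boosting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average Crash Risk and imbalanced-class boosting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the surrogate-risk
model and its assumptions, the labeling and feature pipeline, the boosting
algorithms and the numerical choices behind them, what the synthetic
generator does and does not emulate, and the limitations a user should keep
in mind. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The surrogate-risk model

Car-following risk is scored per time step from four observables: leader
speed $v_l$ (m/s), follower speed $v_f$ (m/s), bumper-to-bumper gap $d$ (m)
and follower acceleration $a_f$ (m/s$^2$), all on a fixed 0.1 s clock. The
stopping-distance margin is

$$\mathrm{DSS}(t) = \frac{v_l^2(t) - v_f^2(t)}{2\mu g} + d(t) - \tau\, v_f(t),$$

the distance by which the follower could still stop behind the leader if
both braked at the friction limit $\mu g$, after a reaction delay $\tau$
driven at the current speed. The instantaneous crash risk converts a
negative margin into a time deficit,

$$\mathrm{CR}(t) = \begin{cases} 0 & \mathrm{DSS}(t) > 0\\
|\mathrm{DSS}(t)|/v_f(t) & \mathrm{DSS}(t) \le 0,\end{cases}$$

and the per-driver statistic is the episode average,
$\mathrm{ACR} = \frac{1}{T}\sum_t \mathrm{CR}(t)\,\Delta t$, in seconds.

Parameters (`risk_params()`): $\mu = 0.7$ (dry-road friction), $g = 9.8$
m/s$^2$, $\tau = 1.5$ s while the follower accelerates and $0.7$ s while it
decelerates or idles, $\Delta t = 0.1$ s. The asymmetric reaction time
reflects that a driver already braking reacts faster than one on the
throttle.

Interpretation choices the formulas leave open, fixed here:

* **Whose acceleration selects $\tau$.** The follower's — the subject whose
  risk is being measured — with the strict sign rule $a_f > 0 \Rightarrow
  1.5$ s, so idling ($a_f = 0$) uses the short reaction time.
* **CR at $v_f = 0$ with $\mathrm{DSS} \le 0$.** Defined as 0. The state is
  reachable only with a stationary follower at (near-)zero gap and leader
  speed; a stationary vehicle cannot close the remaining distance, and
  leaving the ratio undefined would poison episode averages.
* **Normalisation.** $T = N\Delta t$ exactly, so ACR is the arithmetic mean
  of the CR samples. This avoids an off-by-one between the time span
  $(N-1)\Delta t$ and the sample count, and gives ACR the clean invariances
  the tests rely on (sample duplication leaves it unchanged; enlarging every
  gap can only lower it).
* **Units.** Everything internal is SI; the NGSIM-schema reader converts
  `us_customary` feet on ingest (factor 0.3048). The DSS formula is only
  unit-coherent in one system.
* **Gap.** Bumper to bumper: recorded space headway minus the leader's
  vehicle length, clamped at 0 — the physically meaningful collision
  distance.

## 2. Episodes

An episode (`cf_episode`) is a maximal run of frames over which a follower
keeps the same, present leader in an allowed lane with both vehicles
observed at every consecutive frame; runs shorter than 10 s (span
$(N-1)\Delta t$) are dropped. Splitting is strict: a single missing frame or
a momentary change of the preceding-vehicle id ends the run. Real extraction
pipelines sometimes bridge brief tracking dropouts; ours does not, so episode
counts on real data may differ slightly from pipelines that do. Follower
acceleration is taken from the table when present, otherwise as the centred
finite difference of follower speed.

## 3. Labeling by anomaly thresholds

Three rules turn the ACR distribution into binary labels; a driver is
aggressive iff ACR lies strictly above the threshold.

* **Exact two-cluster 1-D k-means** (`kmeans_threshold`). In one dimension
  the optimal two-cluster partition is contiguous in sorted order, so the
  within-cluster sum of squares is minimised exactly by scanning the $n-1$
  sorted split points with prefix sums. No iterative heuristic, no seed, and
  the result is provably optimal — the test suite checks it against
  exhaustive enumeration of *all* two-set partitions up to $n = 12$. The
  threshold is the midpoint of the inter-cluster gap; any point of the open
  gap induces the same partition, and the midpoint is the symmetric choice.
* **IQR rule** (`iqr_threshold`): $Q_3 + 1.5 \cdot (Q_3 - Q_1)$.
* **Percentile** (`percentile_threshold`): the $X$th percentile, default
  $X = 94$, i.e. declaring $100 - X$ percent of drivers aggressive.

Both quantile rules depend on the quantile convention; the package fixes
linear interpolation (R's type 7) and documents it, since the IQR threshold
moves visibly between conventions on 299 data points.

On right-skewed ACR distributions with a large exact-zero mass — typical
when many drivers never have a negative margin — the IQR rule can fall
*below* the k-means threshold and flag more drivers, because $Q_1$ and $Q_3$
both sit in the bulk near zero. The synthetic benchmark shows this ordering;
on data with a milder tail the IQR threshold lands between the k-means and
94th-percentile thresholds. The three rules are alternatives to report side
by side, not a hierarchy.

**Leader–follower independence.** If traffic state, rather than individual
disposition, drove ACR, leaders and followers in the same flow would show
correlated ACR. `leader_follower_correlation()` computes the Pearson
correlation over all episodes whose leader is itself a labeled follower.
Near-zero values support reading ACR as a driver trait.

## 4. Spectral features

Variable-length episodes become fixed-length vectors via the DFT: per
channel (gap, follower speed, follower acceleration — concatenated in that
fixed order) the amplitudes $|\mathrm{DFT}_k|/N$ for $k = 0\ldots14$. The
division by $N$ makes episodes of different lengths comparable and makes the
$k=0$ amplitude the series' absolute mean — for the gap channel, mean
following distance, which is exactly the trait that separates tailgaters.
Fifteen coefficients of a 60 s episode cover 0–0.23 Hz; the "first 15" rule
is taken literally for all lengths. An alternative band-limited mode
(`dft_band_amplitudes`, keep $k/(N\Delta t) \le f_{\max}$, default 1.5 Hz)
is provided for fixed-duration designs where a frequency band, not a
coefficient count, is the natural truncation; the fixed count is the
default because it alone yields equal-length vectors for unequal episode
lengths. No windowing or detrending is applied.

## 5. Boosting under class imbalance

All four AdaBoost-family algorithms share one loop (`boost_fit()`):
AdaBoost.M1 over depth-limited CART weak learners (`rpart`), weighted error
$\varepsilon_t$, vote weight $\alpha_t = \tfrac12\log\frac{1-\varepsilon_t}{\varepsilon_t}$,
multiplicative weight update, rounds with $\varepsilon_t \ge 0.5$ discarded
(stopping boosting), $\varepsilon_t = 0$ ending boosting with that tree
dominating. Scores are the $\alpha$-weighted mean of the trees' positive-class
probabilities, in $[0,1]$; the training error is always bounded by
$\prod_t 2\sqrt{\varepsilon_t(1-\varepsilon_t)}$, and every fit carries that
bound for the tests to check.

The rebalanced variants differ only inside the round: the weak learner is
fitted on a rebalanced sample, while $\varepsilon_t$, $\alpha_t$ and the
update are always computed on the original samples.

* **SMOTEBoost**: synthetic minority rows $x + \lambda(x_{nn} - x)$,
  $\lambda \sim U(0,1)$, $x_{nn}$ among the $k = 5$ nearest minority
  neighbours; synthetic rows carry the mean weight of the real minority rows
  and are discarded after the round.
* **RUSBoost / CUSBoost**: the majority is undersampled to parity
  (`target_ratio = 1`). Within a boosting round the draw is
  weight-proportional without replacement — undersampling the *current
  boosting distribution*. This matters: under hard-label M1 semantics the
  misclassified weight mass is exactly 0.5 after every update, so a
  weight-blind uniform subsample keeps reproducing the previous round's
  mistakes and the weighted error hits 0.5 by round two or three,
  terminating boosting. Weight-proportional sampling restores the
  self-correcting dynamics that the original confidence-rated formulations
  obtain through pseudo-loss. The standalone samplers
  (`random_undersample`, `cluster_undersample`) default to uniform draws per
  their contracts, with `weights` as an opt-in.
* **CUSBoost's cluster step**: k-means (k-means++ seeding, Lloyd iterations,
  default 3 clusters) on the majority rows, allocation proportional to
  cluster size — or weight mass inside boosting — with largest-remainder
  rounding, uniform (or weight-proportional) draws within clusters, and
  bounded re-seeding if a cluster comes back empty.

Initial weights are cost-sensitive (inverse class frequency) for plain
AdaBoost and **uniform for the rebalanced variants**: the resampling already
counters the imbalance, and stacking inverse-frequency weights on top
over-corrects so strongly that the undersampling boosters stall immediately.
The one-shot baselines (`smote_adaboost`, `rus_xgboost`, …) resample the
training set once and then fit without class costs. The gradient-boosted
baseline wraps the xgboost library with `scale_pos_weight` carrying the
class cost; its internals are deliberately not reimplemented.

Numerical safeguards: a round whose learner cannot beat chance is redrawn
with a fresh resample up to five times before the discard-and-stop rule
applies, and if *no* round is ever kept (weak feature sets at high
imbalance can do this) a single weak learner fitted on the original
weighted sample is returned so every configuration yields a usable scorer.
Weak learners are regularised (`minsplit = 10`, `minbucket = 3`,
`cp = 0`, depth 1–3): unregularised trees memorise a 30-row parity
subsample, which both inflates $\alpha$ and destabilises the undersampling
variants. Undersampled rounds preserve original row order — CART split
tie-breaking is order-sensitive, and preserving order keeps the parity
no-op exactly equal to plain AdaBoost on balanced data.

## 6. Evaluation

Precision, recall and F1 use the standard confusion-count definitions with
the 0/0 convention "0 with a warning" (a constant classifier on imbalanced
data should score 0 recall, not crash). PR curves sweep every distinct score
as a threshold with ties grouped; the area is step-wise average precision
$\sum_i (R_i - R_{i-1}) P_i$ with no linear interpolation, which is
known-optimistic in PR space. The tests verify the sweep against brute-force
threshold enumeration and its calibration to prevalence under random
scores — noting that average precision has a small positive finite-$n$ bias
relative to prevalence, which is why the calibration check compares a draw
against the Monte-Carlo spread rather than shrinking the tolerance with
replications.

Cross-validation is stratified 5-fold, repeated 5 times from per-repeat
seeds; class counts per fold differ by at most one (43 positives in 5 folds
gives 8 or 9 per fold). Resampling and grid search (exhaustive, inner
3-fold stratified CV, ties toward fewer rounds then shallower trees) happen
strictly inside training folds. Hard-label metrics use the 0.5 score
threshold; the 25 fold results are averaged unweighted.

## 7. The synthetic generator

`simulate_platoon()` integrates an Intelligent Driver Model platoon at 0.1 s
behind a scripted stop-and-go lead profile (sinusoid plus white noise,
default mean 8 m/s, amplitude 6 m/s, period 40 s — congested freeway
conditions). Driver heterogeneity is two populations: normal (desired time
gap $\mathcal{N}(1.5, 0.2)$ s, minimum gap 2.0 m) and aggressive
($\mathcal{N}(0.6, 0.15)$ s truncated above 0.3 s, minimum gap 0.8 m),
with correspondingly harder accelerations. At a congested 8 m/s equilibrium
a normal driver's gap ($\approx 2.0 + 1.5v$ m) keeps DSS positive, while an
aggressive driver's ($\approx 0.8 + 0.6v$ m) sits below the $0.7 v_f$
reaction-time term — so the aggressive minority accumulates positive ACR and
the majority stays near zero, with overlap induced by noise (below). The
IDM itself is a modelling choice, not a claim about the analysed data: any
collision-free car-following rule with trait heterogeneity would serve.

Two noise layers emulate what video-extracted trajectory data looks like:
behavioural noise on the commanded acceleration (sd 0.2 m/s$^2$ — drivers
are not deterministic controllers) and measurement noise on the recorded
series (speed sd 0.2 m/s, gap sd 0.3 m, acceleration sd 0.4 m/s$^2$;
acceleration noisiest because it is a double derivative of extracted
position). Magnitudes are in the range reported for reconstructed NGSIM-era
data. Without these layers the two populations separate perfectly and every
classifier saturates, which makes downstream comparisons meaningless.

Determinism: one integer seed drives population sampling, the lead profile,
the dynamics noise and the measurement noise through independent derived
streams; identical configurations reproduce bit-identical platoons.

What the generator does **not** emulate: lane changes and multi-lane
interaction (the analysed episodes exclude them by construction), vehicle
length diversity, tracking dropouts and id switches, autocorrelated
measurement error from trajectory smoothing, and drivers whose style varies
over the episode. Passing tests on synthetic data therefore demonstrate
pipeline correctness and qualitative behaviour, not performance on real
trajectories.

## 8. Problem sizes and what the checks show

The test suite runs episode-level unit tests against hand oracles, and a
study-scale check on one seeded platoon of 300 drivers (aggressive fraction
0.14, 60 s episodes) with 5×5-fold CV at 30 boosting rounds — sizes chosen
to exercise the full pipeline at the benchmark's population scale while
keeping a complete run in minutes on one CPU. `scripts/acceptance.R` uses
299 drivers and the same CV geometry.

On this synthetic process the strong, stable findings are: ACR ranks the
ground-truth aggressive minority essentially perfectly (ROC area ≥ 0.9 with
margin); gap-channel DFT features dominate speed+acceleration features by a
wide margin; and leader–follower ACR correlation is near zero. The
imbalance-robustness contrast — rebalancing boosters losing less AUPRC than
cost-sensitive AdaBoost as the labeled minority shrinks from ~6:1 to ~14:1 —
is present but **weak and seed-sensitive** here: cost-sensitive AdaBoost
copes well with the comparatively clean synthetic class boundary, so the
averaged advantage of SMOTEBoost/CUSBoost is small and can invert under
unfavourable fold draws. The acceptance suite asserts it under fixed seeds
and the acceptance script reports the measured drops; users should read
that contrast as dataset-dependent rather than a law.

## 9. Known limitations

* Strict episode splitting (no dropout bridging) can undercount episodes
  relative to extraction pipelines that bridge brief occlusions.
* The $\tau$ regime is decided by the follower's acceleration sign; if a
  data source defines the regime differently (e.g. by the leader's state),
  ACR values shift for episodes near the switching boundary.
* ACR at high imbalance labels "the top tail of one statistic"; classifiers
  trained on features correlated with that statistic inherit threshold
  noise near the cut, which bounds attainable precision at 14:1 regardless
  of algorithm.
* The xgboost baseline is subject to that library's versioning; all other
  algorithms are self-contained and bit-reproducible from seeds.
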