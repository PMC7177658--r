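Package: acrboost
Title: Aggressive-Driver Recognition from Car-Following Trajectories via
    Average Crash Risk and Imbalanced-Class Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Average Crash Risk (ACR) collision-surrogate
    statistic from leader-follower vehicle trajectories sampled at 0.1 s,
    labels aggressive drivers by anomaly-detection thresholds (exact 1-D
    2-means, interquartile-range rule, percentile), extracts truncated
    discrete-Fourier amplitude features from gap, speed and acceleration
    series, and recognises the aggressive minority with from-scratch
    imbalanced-class boosting (cost-sensitive AdaBoost, SMOTEBoost,
    RUSBoost, CUSBoost) plus a gradient-boosted-tree baseline, evaluated
    by precision-recall area under repeated stratified cross-validation.
    Includes an NGSIM-style trajectory reader and an Intelligent-Driver-
    Model platoon simulator with a known aggressive minority so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    rpart,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
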