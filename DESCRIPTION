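Package: moztrack
Title: Classification of Insecticide-Resistance Status from Mosquito Flight Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating insecticide-resistant from
    insecticide-susceptible Anopheles gambiae strains from 2D flight
    trajectories recorded by video tracking. Provides a correlated-random-walk
    simulator of host-seeking flight with a camera-dropout model, moving-window
    track segmentation with interpolation-aware quality filtering, a battery of
    kinematic and shape features (including divider-method fractal dimension,
    tortuosity, centroid-distance and curvature-scale-space descriptors),
    Mann-Whitney/Bonferroni feature selection with Spearman decorrelation,
    trial-grouped cross-validation with SMOTE oversampling for logistic,
    random-forest and gradient-boosted classifiers, track-level majority-vote
    prediction, performance evaluation with an exact Wilcoxon signed-rank test
    against chance, and Shapley-value model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    data.table,
    xgboost,
    ranger,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
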