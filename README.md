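# moztrack

Machine-learning analysis of mosquito flight behaviour: can
insecticide-resistant (IR) and insecticide-susceptible (IS) strains of
*Anopheles gambiae* be told apart from their innate 2D flight trajectories
alone, before any insecticide contact?

`moztrack` implements the full analysis pipeline for video-tracked flight
paths recorded at 50 frames per second around a human-baited, untreated
bednet:

1. **Tracks** `T = {(x_i, y_i, t_i)}` are linearly interpolated onto the
   uniform frame grid, split into fixed-duration moving windows (default
   8 s with 7.5 s overlap), and filtered by a segment-quality score — the
   longest run of consecutively interpolated samples divided by the segment
   length — with the threshold chosen by maximising the mutual information
   between trajectory features and the class label.
2. **Features** (105 per segment): ten kinematic signals (velocity and
   acceleration components, speed, flight-angle change, angular velocity
   and acceleration, centroid distance, curvature) summarised by ten
   statistics (mean, sd, quartiles, skewness, excess kurtosis, zero
   crossings, local extrema), evaluated only at observed samples, plus
   divider-method fractal dimension, tortuosity, convex-hull area and
   curvature-scale-space descriptors.
3. **Selection**: two-sided Mann–Whitney U tests with Bonferroni control at
   FWER < 0.05, then greedy Spearman decorrelation (|rho| > 0.85), computed
   on a held-out tuning partition of 2 trials per strain.
4. **Modelling**: one-trial-per-strain cross-validation (24 folds under the
   study's 3+2+2+2 modelling trial counts), per-fold Z-score
   standardisation and SMOTE class balancing, logistic-regression,
   random-forest or gradient-boosted classifiers, and track-level
   prediction by the mode of the segment predictions.
5. **Evaluation and interpretation**: balanced accuracy (mean per-class
   recall), ROC/PR AUC, MCC, Cohen's kappa, log loss, row-normalised
   confusion matrices, an exact Wilcoxon signed-rank test of the per-fold
   balanced accuracies against chance (Bonferroni-corrected across models),
   and exact tree-Shapley explanations of the boosted model.

Because the original laboratory dataset is available only on request, the
package ships a calibrated synthetic-data generator (`generate_dataset()`):
a first-order autoregressive velocity model with a two-state vertical-drift
Markov chain, sinusoidal speed "dither", reflecting arena boundaries, and a
camera-dropout model moment-matched to the observed inter-observation gap
distribution (median 0.02 s, mean 0.07 s, sd 0.16 s). Its four pseudo-strains
reproduce the published per-strain trial counts, track-duration and speed
scales, and the headline behavioural contrasts: fractal dimension near 1.04
(IR) versus 1.15 (IS), positively skewed and narrower vertical-velocity
distributions for IR, and a stronger IR speed dither.

## Worked example

```r
library(moztrack)

ds <- generate_dataset(seed = 11)          # 17 trials, 4 pseudo-strains
round(gap_statistics(ds$tracks), 3)
#> median   mean     sd
#>  0.020  0.069  0.158

report <- run_pipeline(ds$tracks, task = "IR_vs_IS", seed = 3)
report
#> Task IR_vs_IS, gradient_boosted_trees, window 8 s / overlap 7.5 s, 24 folds
#>   accuracy           1.000 (1.000-1.000)
#>   balanced_accuracy  1.000 (1.000-1.000)
#>   roc_auc            1.000 (1.000-1.000)
#>   signed-rank vs chance: p = 1.19e-07 (corrected 7.15e-07)

round(report$confusion, 1)
#>       IR  IS
#>   IR 100   0
#>   IS   0 100

sh <- explain_model(report$best_fold$model, report$best_fold$test_X)
head(sh$ranking, 5)
#> [1] "angacc_q3" "ax_kurtosis" "ax_n_local_max" "ax_q3" "ax_sd"
```

The gap statistics match the calibration targets of the recording process.
The injected IR/IS contrast is strong enough that every fold classifies
every held-out track correctly — the synthetic task demonstrates that the
pipeline recovers a real class signal (and collapses to chance when labels
are permuted: `run_pipeline(..., permute_labels = TRUE)` gives balanced
accuracy ≈ 0.5), not that real mosquito data are this separable. The
signed-rank p-value sits at its exact floor for 24 uniformly positive folds,
`6 × 2/2^24 = 7.15e-7`. The Shapley ranking surfaces the
persistence-linked kinematics that the generator uses to separate the
classes.

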