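# End-to-end pipeline driver: partition -> quality threshold and feature
# selection on the tuning trials -> trial-grouped cross-validation on the
# modelling trials -> evaluation.

TASKS <- c("IR_vs_IS", "IS_pair", "IR_pair", "multiclass")

task_spec <- function(task, ir_strains = c("Banfora", "VK7"),
                      is_strains = c("Kisumu", "Ngoussu")) {
  switch(task,
    IR_vs_IS = list(strains = NULL,
                    labeller = function(s) label_ir_is(s, ir_strains),
                    chance = 0.5),
    IS_pair = list(strains = is_strains, labeller = label_strain,
                   chance = 0.5),
    IR_pair = list(strains = ir_strains, labeller = label_strain,
                   chance = 0.5),
    multiclass = list(strains = NULL, labeller = label_strain,
                      chance = 0.25))
}

#' Run the full classification pipeline
#'
#' Executes the complete analysis on a track table: minimum-duration
#' filtering, a seeded trial-level split into tuning and modelling
#' partitions, segment-quality threshold selection and Mann-Whitney /
#' Spearman feature selection on the tuning partition only, then
#' one-trial-per-strain cross-validation on the modelling partition with
#' per-fold standardisation, SMOTE balancing, classifier training and
#' track-level majority-vote prediction, and finally metric aggregation, a
#' pooled confusion matrix and the exact signed-rank test against chance.
#'
#' @param tracks Track `data.frame` (see [read_tracks()]).
#' @param task One of `"IR_vs_IS"`, `"IS_pair"`, `"IR_pair"`,
#'   `"multiclass"`.
#' @param model_kind Classifier family (see [train_classifier()]).
#' @param window_s,overlap_s Moving-window parameters, s; defaults are the
#'   tuned values of the gradient-boosted IR-vs-IS task.
#' @param fps Frames per second.
#' @param params Hyperparameter list passed to [train_classifier()].
#' @param seed Integer seed governing the partition, SMOTE and the
#'   classifiers.
#' @param n_tuning_per_strain Trials per strain in the tuning partition.
#' @param quality_grid Candidate quality thresholds.
#' @param permute_labels Permute track-level labels in the modelling
#'   partition (chance-level control).
#' @param n_models Bonferroni family size for the significance test.
#' @param keep_best_fold Keep the best fold's fitted model and test matrix
#'   (for Shapley explanation).
#' @return An object of class `moz_report`: list with `task`, `report`
#'   (aggregated metrics), `fold_metrics`, `predictions` (pooled),
#'   `confusion` (row-normalised percentages), `significance`,
#'   `quality_threshold`, `selected_features`, `partition`, and `best_fold`.
#' @export
run_pipeline <- function(tracks, task = "IR_vs_IS",
                         model_kind = "gradient_boosted_trees",
                         window_s = 8, overlap_s = 7.5, fps = 50,
                         params = list(), seed = 1L,
                         n_tuning_per_strain = 2L,
                         quality_grid = seq(0, 1, length.out = 21),
                         permute_labels = FALSE, n_models = 6L,
                         keep_best_fold = TRUE) {
  task <- match.arg(task, TASKS)
  spec <- task_spec(task)
  if (!is.null(spec$strains))
    tracks <- tracks[tracks$strain %in% spec$strains, , drop = FALSE]
  tracks <- filter_min_duration(tracks, 1.0)
  part <- partition_dataset(tracks, n_tuning_per_strain, seed = seed)
  cfg <- segmentation_config(window_s, overlap_s, fps)

  # --- tuning partition: quality threshold + feature selection (frozen) ---
  tune_tracks <- tracks[tracks$trial_id %in% part$tuning$trial_id, ]
  tune_segs <- segment_collection(tune_tracks, cfg)
  if (length(tune_segs) == 0L) stop("tuning partition yielded no segments")
  tune_fm <- build_feature_matrix(tune_segs, fps)
  tune_fm$label <- spec$labeller(tune_fm$strain)
  thr <- select_quality_threshold(tune_fm$quality,
                                  tune_fm[, feature_names(tune_fm)],
                                  tune_fm$label, quality_grid)
  tune_keep <- tune_fm$quality <= as.numeric(thr)
  sel <- select_features(tune_fm[tune_keep, , drop = FALSE],
                         tune_fm$label[tune_keep])
  feats <- sel$kept
  if (length(feats) == 0L) stop("feature selection retained no features")

  # --- modelling partition: grouped cross-validation ---
  model_tracks <- tracks[tracks$trial_id %in% part$modelling$trial_id, ]
  segs <- segment_collection(model_tracks, cfg)
  fm <- build_feature_matrix(segs, fps)
  fm <- fm[fm$quality <= as.numeric(thr), , drop = FALSE]
  fm$label <- spec$labeller(fm$strain)
  if (permute_labels) {
    set.seed(seed + 1L)
    key <- paste(fm$trial_id, fm$track_id, sep = "//")
    track_lab <- tapply(as.character(fm$label), key, `[`, 1L)
    perm <- stats::setNames(sample(track_lab), names(track_lab))
    fm$label <- factor(perm[key], levels = levels(fm$label))
  }
  folds <- enumerate_folds(part$modelling)
  fold_results <- lapply(folds, function(fold)
    run_fold(fm, feats, fold, kind = model_kind, params = params,
             seed = seed))
  ok <- !vapply(fold_results, is.null, logical(1))
  fold_results <- fold_results[ok]
  if (length(fold_results) == 0L) stop("no fold produced test predictions")
  fold_metrics <- lapply(fold_results, `[[`, "metrics")
  preds <- do.call(rbind, lapply(seq_along(fold_results), function(i)
    cbind(fold = i, fold_results[[i]]$preds)))
  bas <- vapply(fold_metrics, `[[`, numeric(1), "balanced_accuracy")
  best <- which.max(bas)
  structure(list(
    task = task, model_kind = model_kind,
    window_s = window_s, overlap_s = overlap_s, seed = seed,
    report = aggregate_folds(fold_metrics),
    fold_metrics = fold_metrics,
    predictions = preds,
    confusion = pooled_confusion(preds),
    significance = wilcoxon_vs_chance(bas, spec$chance, n_models),
    quality_threshold = as.numeric(thr),
    selected_features = feats,
    selection_table = sel$table,
    partition = part,
    feature_matrix = fm,
    best_fold = if (keep_best_fold) fold_results[[best]] else NULL),
    class = "moz_report")
}

#' @export
print.moz_report <- function(x, ...) {
  cat(sprintf("Task %s, %s, window %g s / overlap %g s, %d folds\n",
              x$task, x$model_kind, x$window_s, x$overlap_s,
              length(x$fold_metrics)))
  main <- x$report[x$report$metric %in%
                     c("balanced_accuracy", "accuracy", "roc_auc"), ]
  for (i in seq_len(nrow(main)))
    cat(sprintf("  %-18s %.3f (%.3f-%.3f)\n", main$metric[i], main$mean[i],
                main$min[i], main$max[i]))
  cat(sprintf("  signed-rank vs chance: p = %.3g (corrected %.3g)\n",
              x$significance$p, x$significance$p_corrected))
  invisible(x)
}
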