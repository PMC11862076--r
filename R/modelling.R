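# Dataset partitioning, trial-grouped fold enumeration, preprocessing
# (standardisation + SMOTE), classifier training, track-level vote
# aggregation and grid-search tuning.

#' Partition trials into tuning and modelling sets
#'
#' Randomly assigns `n_tuning_per_strain` trials of each strain to the
#' tuning partition (used for threshold selection, feature selection and
#' hyperparameter tuning); the remainder form the modelling partition.
#' Splitting by whole trials prevents any track from appearing in both
#' partitions.
#'
#' @param trials `data.frame` with columns `strain`, `trial_id` (one row per
#'   trial), or a track `data.frame` from which trials are derived.
#' @param n_tuning_per_strain Trials per strain assigned to tuning
#'   (default 2).
#' @param seed Integer seed.
#' @return List with `tuning` and `modelling`, each a `data.frame` of
#'   `strain`, `trial_id`.
#' @export
partition_dataset <- function(trials, n_tuning_per_strain = 2L, seed = 1L) {
  if (!is.null(trials$t)) {  # a track table: reduce to its trials
    trials <- unique(trials[, c("strain", "trial_id")])
  }
  trials <- trials[order(trials$strain, trials$trial_id), , drop = FALSE]
  counts <- table(trials$strain)
  if (any(counts <= n_tuning_per_strain))
    stop("every strain needs more than ", n_tuning_per_strain,
         " trials (modelling set would be empty for: ",
         paste(names(counts)[counts <= n_tuning_per_strain], collapse = ", "),
         ")")
  set.seed(seed)
  tuning_ids <- unlist(lapply(split(trials$trial_id, trials$strain),
                              function(ids) sample(ids, n_tuning_per_strain)))
  tune <- trials[trials$trial_id %in% tuning_ids, , drop = FALSE]
  model <- trials[!trials$trial_id %in% tuning_ids, , drop = FALSE]
  rownames(tune) <- rownames(model) <- NULL
  list(tuning = tune, modelling = model)
}

#' Enumerate one-trial-per-strain folds
#'
#' Builds every fold whose training set contains exactly one trial of each
#' strain, with all remaining modelling trials in the test set. The fold
#' count is the product of the per-strain trial counts (e.g. 3 x 2 x 2 x 2 =
#' 24 under the study's modelling partition); ordering is lexicographic by
#' trial id.
#'
#' @param modelling_trials `data.frame` of `strain`, `trial_id`.
#' @return List of folds, each a list with `fold_id`, `train_trials`,
#'   `test_trials`.
#' @export
enumerate_folds <- function(modelling_trials) {
  by_strain <- split(modelling_trials$trial_id, modelling_trials$strain)
  if (any(lengths(by_strain) == 0L)) stop("a strain has no modelling trials")
  by_strain <- lapply(by_strain, sort)
  combos <- expand.grid(rev(by_strain), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(by_strain)), drop = FALSE]
  all_ids <- modelling_trials$trial_id
  folds <- lapply(seq_len(nrow(combos)), function(i) {
    train <- unlist(combos[i, ], use.names = FALSE)
    test <- setdiff(all_ids, train)
    if (length(test) == 0L)
      warning("fold ", i, " has an empty test set")
    list(fold_id = i, train_trials = train, test_trials = test)
  })
  folds
}

#' Z-score standardisation fitted on the training rows
#'
#' Centres and scales every column by the training mean and (population,
#' `n` denominator) standard deviation; the test rows are transformed with
#' the training parameters. Constant training columns are centred only and
#' flagged.
#'
#' @param train Numeric `data.frame`/matrix of training rows.
#' @param apply_to Optional rows to transform with the fitted parameters.
#' @return List with `train`, `apply_to` (or `NULL`), `center`, `scale` and
#'   `constant` (names of degenerate columns).
#' @export
standardise <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  center <- colMeans(train)
  scale_ <- sqrt(colMeans(sweep(train, 2, center)^2))  # population sd
  constant <- colnames(train)[scale_ == 0]
  if (length(constant) > 0L)
    warning("constant training column(s) centred only: ",
            paste(constant, collapse = ", "))
  scale_[scale_ == 0] <- 1
  tr <- sweep(sweep(train, 2, center), 2, scale_, "/")
  ap <- NULL
  if (!is.null(apply_to)) {
    ap <- as.matrix(apply_to)[, colnames(train), drop = FALSE]
    ap <- sweep(sweep(ap, 2, center), 2, scale_, "/")
  }
  list(train = tr, apply_to = ap, center = center, scale = scale_,
       constant = constant)
}

#' SMOTE oversampling of the minority class
#'
#' Balances the class counts by synthesising minority-class rows on the
#' line segments between each drawn minority sample and one of its `k`
#' nearest minority neighbours (Euclidean distance). Synthetic rows are
#' flagged so they can be excluded from track-level evaluation.
#'
#' @param X Numeric matrix of training rows.
#' @param labels Class label per row (two or more classes; every class is
#'   raised to the majority count).
#' @param k Number of nearest neighbours (default 5, capped at the class
#'   size minus one).
#' @param seed Integer seed.
#' @return List with `X`, `labels` and logical `synthetic` flags.
#' @export
oversample_smote <- function(X, labels, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  counts <- table(labels)
  n_max <- max(counts)
  if (any(counts < 2L))
    stop("SMOTE requires at least 2 samples in every class")
  set.seed(seed)
  add_X <- list(); add_y <- list()
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0L) next
    idx <- which(labels == cl)
    M <- X[idx, , drop = FALSE]
    kk <- min(k, nrow(M) - 1L)
    D <- as.matrix(stats::dist(M))
    diag(D) <- Inf
    nn <- apply(D, 1, function(d) order(d)[seq_len(kk)], simplify = FALSE)
    base_i <- sample.int(nrow(M), need, replace = TRUE)
    nb_i <- vapply(base_i, function(i) nn[[i]][sample.int(kk, 1L)],
                   integer(1))
    u <- stats::runif(need)
    add_X[[cl]] <- M[base_i, , drop = FALSE] +
      u * (M[nb_i, , drop = FALSE] - M[base_i, , drop = FALSE])
    add_y[[cl]] <- rep(cl, need)
  }
  if (length(add_X) == 0L)
    return(list(X = X, labels = labels,
                synthetic = rep(FALSE, nrow(X))))
  Xs <- rbind(X, do.call(rbind, add_X))
  ys <- factor(c(as.character(labels), unlist(add_y)),
               levels = levels(labels))
  list(X = Xs, labels = ys,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs) - nrow(X))))
}

#' Train a segment classifier
#'
#' Fits one of the three model families on a standardised (and typically
#' SMOTE-balanced) training matrix: logistic regression (`stats::glm`, or
#' `nnet::multinom` for more than two classes), random forest
#' (`ranger`), or gradient-boosted trees (`xgboost`). Tree ensembles are
#' seeded and single-threaded for reproducibility.
#'
#' @param kind One of `"logistic_regression"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`.
#' @param X Numeric training matrix (rows = segments).
#' @param labels Class label per row.
#' @param params Named list of hyperparameters. Recognised:
#'   `num_trees`/`nrounds`, `max_depth`, `eta` (boosting learning rate).
#' @param seed Integer seed.
#' @return An object of class `moz_model`.
#' @export
train_classifier <- function(kind = c("gradient_boosted_trees",
                                      "random_forest",
                                      "logistic_regression"),
                             X, labels, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in the training matrix")
  labels <- as.factor(labels)
  lev <- levels(labels)
  set.seed(seed)
  fit <- switch(kind,
    logistic_regression = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- labels
      if (length(lev) == 2L) {
        stats::glm(.y ~ ., data = df, family = stats::binomial())
      } else {
        nnet::multinom(.y ~ ., data = df, trace = FALSE,
                       MaxNWts = 1e5, maxit = 200)
      }
    },
    random_forest = ranger::ranger(
      x = X, y = labels, probability = TRUE,
      num.trees = params$num_trees %||% 300L,
      max.depth = params$max_depth %||% 0L,
      seed = seed, num.threads = 1L),
    gradient_boosted_trees = {
      y_num <- as.integer(labels) - 1L
      obj <- if (length(lev) == 2L) "binary:logistic" else "multi:softprob"
      xgb_params <- list(objective = obj,
                         max_depth = params$max_depth %||% 4L,
                         eta = params$eta %||% 0.1,
                         nthread = 1L, seed = seed)
      if (length(lev) > 2L) xgb_params$num_class <- length(lev)
      xgboost::xgb.train(params = xgb_params,
                         data = xgboost::xgb.DMatrix(X, label = y_num),
                         nrounds = params$nrounds %||% params$num_trees %||%
                           100L, verbose = 0)
    })
  structure(list(kind = kind, fit = fit, levels = lev,
                 features = colnames(X)), class = "moz_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-segment class probabilities
#'
#' @param model A `moz_model` from [train_classifier()].
#' @param X Numeric matrix of segments (standardised with the training
#'   parameters).
#' @return Matrix of class probabilities, one column per class level.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  lev <- model$levels
  p <- switch(model$kind,
    logistic_regression = {
      df <- data.frame(X, check.names = FALSE)
      if (length(lev) == 2L) {
        p1 <- stats::predict(model$fit, newdata = df, type = "response")
        cbind(1 - p1, p1)
      } else {
        as.matrix(stats::predict(model$fit, newdata = df, type = "probs"))
      }
    },
    random_forest = stats::predict(model$fit, data = X,
                                   num.threads = 1L)$predictions,
    gradient_boosted_trees = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
      if (length(lev) == 2L) cbind(1 - pr, pr)
      else matrix(pr, ncol = length(lev), byrow = TRUE)
    })
  colnames(p) <- lev
  p
}

#' Aggregate segment predictions into track predictions
#'
#' Each segment is classified independently (argmax probability); the
#' track-level label is the mode of its segments' labels. Ties are broken
#' by the higher mean predicted probability across the track's segments.
#'
#' @param probs Segment-level probability matrix from [predict_proba()].
#' @param track_ids Track identifier per segment.
#' @param true_labels True class per segment (constant within a track).
#' @return `data.frame` with one row per track: `track_id`, `true`, `pred`,
#'   `n_segments` and mean `prob_<class>` columns.
#' @export
predict_tracks <- function(probs, track_ids, true_labels) {
  lev <- colnames(probs)
  seg_pred <- lev[max.col(probs, ties.method = "first")]
  out <- lapply(split(seq_along(track_ids), track_ids), function(ii) {
    votes <- table(factor(seg_pred[ii], levels = lev))
    mp <- colMeans(probs[ii, , drop = FALSE])
    top <- names(votes)[votes == max(votes)]
    final <- if (length(top) == 1L) top else top[which.max(mp[top])]
    data.frame(track_id = track_ids[ii[1]],
               true = as.character(true_labels[ii[1]]), pred = final,
               n_segments = length(ii),
               t(mp), check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[-(1:4)] <- paste0("prob_", lev)
  rownames(out) <- NULL
  out
}

#' Cross-validated grid search on the tuning partition
#'
#' Scores every grid point by re-segmenting the tuning tracks at its window
#' parameters, running `n_folds` one-trial-per-strain folds (a seeded
#' subsample of the full combination set), and averaging track-level
#' balanced accuracy. The arg-max configuration is returned; ties break by
#' grid order.
#'
#' @param tracks Track `data.frame` restricted to the tuning trials.
#' @param grid `data.frame` of configurations with columns `window_s`,
#'   `overlap_s` and optionally `kind`, `nrounds`, `max_depth`, `eta`,
#'   `num_trees`.
#' @param labeller Function mapping a strain vector to class labels.
#' @param n_folds Folds per grid point (default 5).
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @param smote_k SMOTE neighbourhood size.
#' @return List with `best` (the winning grid row) and `results` (the grid
#'   with a `balanced_accuracy` column).
#' @export
grid_search <- function(tracks, grid, labeller = label_ir_is,
                        n_folds = 5L, fps = 50, seed = 1L, smote_k = 5L) {
  stopifnot(nrow(grid) >= 1L)
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, , drop = FALSE]
    cfg <- segmentation_config(g$window_s, g$overlap_s, fps)
    segs <- segment_collection(tracks, cfg)
    if (length(segs) == 0L) {
      warning("grid point ", gi, " produced zero segments; scored 0")
      scores[gi] <- 0
      next
    }
    fm <- build_feature_matrix(segs, fps)
    fm$label <- labeller(fm$strain)
    trials <- unique(fm[, c("strain", "trial_id")])
    folds <- enumerate_folds(trials)
    set.seed(seed)
    use <- if (length(folds) > n_folds)
      folds[sort(sample.int(length(folds), n_folds))] else folds
    bas <- vapply(use, function(fold) {
      r <- run_fold(fm, feature_names(fm), fold,
                    kind = g$kind %||% "gradient_boosted_trees",
                    params = as.list(g[intersect(names(g),
                      c("nrounds", "max_depth", "eta", "num_trees"))]),
                    seed = seed, smote_k = smote_k)
      if (is.null(r)) NA_real_ else r$metrics[["balanced_accuracy"]]
    }, numeric(1))
    scores[gi] <- mean(bas, na.rm = TRUE)
  }
  results <- cbind(grid, balanced_accuracy = scores)
  list(best = results[which.max(scores), , drop = FALSE], results = results)
}

# train/evaluate one fold on a labelled feature matrix; NULL if the test
# set lacks tracks
run_fold <- function(fm, feats, fold, kind, params = list(), seed = 1L,
                     smote_k = 5L) {
  tr <- fm$trial_id %in% fold$train_trials
  te <- fm$trial_id %in% fold$test_trials
  if (!any(te) || !any(tr)) return(NULL)
  if (length(unique(fm$label[tr])) < 2L) return(NULL)
  st <- standardise(fm[tr, feats, drop = FALSE], fm[te, feats, drop = FALSE])
  sm <- oversample_smote(st$train, fm$label[tr], k = smote_k, seed = seed)
  model <- train_classifier(kind, sm$X, sm$labels, params, seed = seed)
  probs <- predict_proba(model, st$apply_to)
  track_key <- paste(fm$trial_id[te], fm$track_id[te], sep = "//")
  preds <- predict_tracks(probs, track_key, fm$label[te])
  metrics <- compute_metrics(preds)
  list(model = model, preds = preds, metrics = metrics,
       test_X = st$apply_to, test_meta = fm[te, c("strain", "trial_id",
                                                  "track_id", "label")])
}

#' Label mappers for the classification tasks
#'
#' `label_ir_is` maps strains to IR/IS resistance classes;
#' `label_strain` keeps the strain itself (multiclass).
#'
#' @param strain Character vector of strain names.
#' @param ir_strains Strains in the resistant class.
#' @return Factor of class labels.
#' @export
label_ir_is <- function(strain, ir_strains = c("Banfora", "VK7")) {
  factor(ifelse(strain %in% ir_strains, "IR", "IS"), levels = c("IS", "IR"))
}

#' @rdname label_ir_is
#' @export
label_strain <- function(strain) factor(strain)
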