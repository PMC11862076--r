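trial_table <- function(counts) {
  do.call(rbind, lapply(names(counts), function(s)
    data.frame(strain = s,
               trial_id = sprintf("%s_%d", s, seq_len(counts[[s]])))))
}

test_that("the trial partition matches the study's 8 + 9 design", {
  trials <- trial_table(c(Kisumu = 5, Ngoussu = 4, Banfora = 4, VK7 = 4))
  part <- partition_dataset(trials, 2, seed = 3)
  expect_equal(nrow(part$tuning), 8L)
  expect_equal(nrow(part$modelling), 9L)
  expect_equal(as.integer(table(part$tuning$strain)), rep(2L, 4))
  expect_length(intersect(part$tuning$trial_id, part$modelling$trial_id), 0L)

  part2 <- partition_dataset(trials, 2, seed = 3)
  expect_identical(part, part2)

  expect_error(partition_dataset(trial_table(c(A = 2, B = 2)), 2),
               "modelling set would be empty")
})

test_that("fold enumeration is the product of per-strain trial counts", {
  f24 <- enumerate_folds(trial_table(c(A = 3, B = 2, C = 2, D = 2)))
  expect_length(f24, 24L)
  f16 <- enumerate_folds(trial_table(c(A = 2, B = 2, C = 2, D = 2)))
  expect_length(f16, 16L)

  # every fold: one trial per strain in training, disjoint train/test
  for (f in f24) {
    expect_length(f$train_trials, 4L)
    expect_equal(sort(sub("_\\d+$", "", f$train_trials)),
                 c("A", "B", "C", "D"))
    expect_length(intersect(f$train_trials, f$test_trials), 0L)
    expect_length(c(f$train_trials, f$test_trials), 9L)
  }

  # combinatorial oracle on random counts
  set.seed(1)
  for (i in 1:5) {
    counts <- sample(1:4, 3, replace = TRUE)
    names(counts) <- c("X", "Y", "Z")
    expect_length(suppressWarnings(enumerate_folds(trial_table(counts))),
                  prod(counts))
  }

  expect_warning(enumerate_folds(trial_table(c(A = 1, B = 1))), "empty test")
})

test_that("standardisation uses training parameters with the population sd", {
  st <- standardise(data.frame(f = c(1, 2, 3)), data.frame(f = c(2, 4)))
  expect_equal(as.numeric(st$train), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(as.numeric(st$apply_to)[1], 0)  # test value at the train mean
  expect_equal(unname(st$scale), sqrt(2 / 3))

  expect_warning(st2 <- standardise(data.frame(a = c(5, 5, 5))), "constant")
  expect_equal(as.numeric(st2$train), c(0, 0, 0))
  expect_equal(st2$constant, "a")
})

test_that("SMOTE balances classes with synthetic points on neighbour segments", {
  set.seed(4)
  X <- matrix(rnorm(320), ncol = 2)
  y <- rep(c("maj", "min"), c(100, 60))
  sm <- oversample_smote(X, y, k = 5, seed = 2)
  expect_equal(as.integer(table(sm$labels)), c(100L, 100L))
  expect_equal(sum(sm$synthetic), 40L)
  expect_false(any(sm$synthetic[1:160]))

  # already balanced: identity
  sm0 <- oversample_smote(X[1:100, ], rep(c("a", "b"), 50), seed = 1)
  expect_equal(nrow(sm0$X), 100L)
  expect_false(any(sm0$synthetic))

  # minority of two points: synthetic samples lie on the connecting segment
  X2 <- rbind(matrix(rnorm(40), ncol = 2),
              c(0, 0), c(1, 2))
  y2 <- rep(c("maj", "min"), c(20, 2))
  sm2 <- oversample_smote(X2, y2, k = 5, seed = 3)
  syn <- sm2$X[sm2$synthetic, , drop = FALSE]
  expect_equal(nrow(syn), 18L)
  u <- syn[, 1]
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(syn[, 2], 2 * u, tolerance = 1e-12)

  expect_error(oversample_smote(X2, rep(c("maj", "min"), c(21, 1))),
               "at least 2")
})

test_that("all three classifier families separate a toy problem and are seeded", {
  set.seed(6)
  n <- 120
  X <- cbind(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             f2 = rnorm(n))
  y <- factor(rep(c("IS", "IR"), each = n / 2), levels = c("IS", "IR"))
  for (kind in c("logistic_regression", "random_forest",
                 "gradient_boosted_trees")) {
    m <- train_classifier(kind, X, y, seed = 5)
    p <- predict_proba(m, X)
    expect_equal(colnames(p), c("IS", "IR"))
    acc <- mean(colnames(p)[max.col(p)] == as.character(y))
    expect_equal(acc, 1.0)
  }
  # determinism of the tree ensembles
  for (kind in c("random_forest", "gradient_boosted_trees")) {
    p1 <- predict_proba(train_classifier(kind, X, y, seed = 7), X)
    p2 <- predict_proba(train_classifier(kind, X, y, seed = 7), X)
    expect_identical(p1, p2)
  }
  expect_error(train_classifier("gradient_boosted_trees",
                                cbind(a = c(1, NA, 3)), factor(c(1, 2, 1))),
               "non-finite")
})

test_that("label-independent features yield chance-level held-out accuracy", {
  set.seed(8)
  n <- 2000
  X <- matrix(rnorm(n * 5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(sample(c("IS", "IR"), n, replace = TRUE),
              levels = c("IS", "IR"))
  m <- train_classifier("gradient_boosted_trees", X[1:1000, ], y[1:1000],
                        params = list(nrounds = 50), seed = 1)
  p <- predict_proba(m, X[1001:2000, ])
  pred <- colnames(p)[max.col(p)]
  cm <- table(y[1001:2000], factor(pred, levels = c("IS", "IR")))
  ba <- mean(diag(cm) / rowSums(cm))
  expect_lt(abs(ba - 0.5), 0.05)
})

test_that("track votes use the segment mode with probability tie-breaks", {
  lev <- c("IS", "IR")
  pm <- function(p_ir) cbind(IS = 1 - p_ir, IR = p_ir)

  # mode [IR, IR, IS] -> IR
  pr <- predict_tracks(pm(c(0.9, 0.8, 0.1)), rep("tk1", 3),
                       rep("IR", 3))
  expect_equal(pr$pred, "IR")
  expect_equal(pr$n_segments, 3L)

  # tie [IR, IS] with mean prob(IR) = 0.45 -> IS
  pr2 <- predict_tracks(pm(c(0.8, 0.1)), rep("tk1", 2), rep("IR", 2))
  expect_equal(pr2$pred, "IS")

  # single segment: its own label
  pr3 <- predict_tracks(pm(0.7), "tk1", "IR")
  expect_equal(pr3$pred, "IR")

  # mean probabilities are carried per track
  expect_equal(pr2$prob_IR, 0.45)
})

test_that("grid search returns the argmax with deterministic tie-breaking", {
  set.seed(10)
  ds <- generate_dataset(tiny_profiles(n_trials = 2, tracks = 5),
                         dropout = NULL, seed = 5)
  grid1 <- data.frame(window_s = 2, overlap_s = 1)
  g1 <- grid_search(ds$tracks, grid1, n_folds = 2, seed = 1,
                    labeller = function(s) label_ir_is(s, "S_IR"))
  expect_equal(nrow(g1$results), 1L)
  expect_equal(g1$best$window_s, 2)

  # two identical grid points: the first wins
  grid2 <- rbind(grid1, grid1)
  g2 <- grid_search(ds$tracks, grid2, n_folds = 2, seed = 1,
                    labeller = function(s) label_ir_is(s, "S_IR"))
  expect_equal(g2$results$balanced_accuracy[1],
               g2$results$balanced_accuracy[2])
  expect_equal(rownames(g2$best), "1")
})

test_that("fold runs never leak trials and exclude synthetic rows from testing", {
  ds <- generate_dataset(tiny_profiles(n_trials = 3, tracks = 5),
                         dropout = NULL, seed = 6)
  cfg <- segmentation_config(2, 1, 50)
  fm <- build_feature_matrix(moztrack:::segment_collection(ds$tracks, cfg), 50)
  fm$label <- label_ir_is(fm$strain, "S_IR")
  trials <- unique(fm[, c("strain", "trial_id")])
  folds <- enumerate_folds(trials)
  feats <- c("vy_q3", "fractal_dimension", "speed_mean", "vx_sd")
  for (fold in folds[1:2]) {
    r <- moztrack:::run_fold(fm, feats, fold, "gradient_boosted_trees",
                             params = list(nrounds = 20), seed = 1)
    # every evaluated track comes from a test trial
    test_keys <- unique(paste(fm$trial_id[fm$trial_id %in% fold$test_trials],
                              fm$track_id[fm$trial_id %in% fold$test_trials],
                              sep = "//"))
    expect_true(all(r$preds$track_id %in% test_keys))
    # the number of evaluated segments equals the number of real test rows
    expect_equal(nrow(r$test_X), sum(fm$trial_id %in% fold$test_trials))
  }
})
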