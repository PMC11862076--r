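# Shapley-value interpretation of the fitted tree model and population-level
# descriptive contrasts.

#' Shapley explanation of a fitted model
#'
#' For gradient-boosted models, exact tree-Shapley contributions are
#' computed per segment in margin (log-odds) space; positive contributions
#' push the prediction towards the second class level (IR under the default
#' labelling). The contributions plus the base value reproduce the model's
#' margin output exactly (additivity). For non-tree models only the
#' importance ranking is available, via seeded permutation importance, and
#' the result is flagged as an approximation.
#'
#' @param model A `moz_model` from [train_classifier()].
#' @param X Standardised feature matrix of the segments to explain.
#' @param labels Labels for `X`; only needed for the permutation fallback.
#' @param seed Seed for the permutation fallback.
#' @return An object of class `shap_result`: list with `contrib` (segments
#'   x features), `base_value`, `ranking` (features by decreasing mean
#'   absolute contribution), `mean_abs` and `approximate`.
#' @export
explain_model <- function(model, X, labels = NULL, seed = 1L) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  if (model$kind == "gradient_boosted_trees") {
    if (length(model$levels) != 2L)
      stop("Shapley explanation implemented for the binary model")
    contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(X),
                              predcontrib = TRUE)
    base <- contrib[1, ncol(contrib)]  # bias term is the last column
    contrib <- contrib[, -ncol(contrib), drop = FALSE]
    approx <- FALSE
  } else {
    if (is.null(labels))
      stop("labels are required for permutation importance on non-tree models")
    set.seed(seed)
    base_ba <- balanced_accuracy_of(model, X, labels)
    imp <- vapply(seq_len(ncol(X)), function(j) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      base_ba - balanced_accuracy_of(model, Xp, labels)
    }, numeric(1))
    contrib <- matrix(rep(imp, each = nrow(X)), nrow = nrow(X),
                      dimnames = list(NULL, colnames(X)))
    base <- NA_real_
    approx <- TRUE
    warning("non-tree model: ranking via permutation importance (approximate)")
  }
  mean_abs <- colMeans(abs(contrib))
  ranking <- names(mean_abs)[order(-mean_abs, names(mean_abs))]
  structure(list(contrib = contrib, base_value = base,
                 ranking = ranking,
                 mean_abs = mean_abs, approximate = approx),
            class = "shap_result")
}

balanced_accuracy_of <- function(model, X, labels) {
  p <- predict_proba(model, X)
  pred <- factor(colnames(p)[max.col(p, ties.method = "first")],
                 levels = model$levels)
  truth <- factor(labels, levels = model$levels)
  cm <- table(truth, pred)
  mean(diag(cm) / rowSums(cm), na.rm = TRUE)
}

#' Export Shapley summaries
#'
#' Builds (and optionally writes as CSV) the tables behind the standard
#' Shapley figures: the bar table of mean absolute contributions, the
#' summary table of per-segment contributions paired with feature values,
#' and scatter tables for chosen features.
#'
#' @param shap A `shap_result` from [explain_model()].
#' @param X The feature matrix that was explained (same rows).
#' @param features Features for scatter tables (default: top 5 of the
#'   ranking).
#' @param dir Output directory for CSV files (`shap_bar.csv`,
#'   `shap_summary.csv`, `shap_scatter_<feature>.csv`); `NULL` skips
#'   writing.
#' @param top_k Rows of the bar table (default all).
#' @return List with `bar`, `summary` and `scatter` tables.
#' @export
rank_and_export <- function(shap, X, features = utils::head(shap$ranking, 5),
                            dir = NULL, top_k = Inf) {
  X <- as.matrix(X)
  bar <- data.frame(feature = shap$ranking,
                    mean_abs_shap = shap$mean_abs[shap$ranking],
                    row.names = NULL)
  if (is.finite(top_k)) bar <- utils::head(bar, top_k)
  nseg <- nrow(shap$contrib)
  summary_tab <- data.frame(
    segment = rep(seq_len(nseg), times = ncol(shap$contrib)),
    feature = rep(colnames(shap$contrib), each = nseg),
    value = as.vector(X[, colnames(shap$contrib)]),
    shap = as.vector(shap$contrib))
  scatter <- lapply(features, function(f)
    data.frame(value = X[, f], shap = shap$contrib[, f]))
  names(scatter) <- features
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    data.table::fwrite(bar, file.path(dir, "shap_bar.csv"))
    data.table::fwrite(summary_tab, file.path(dir, "shap_summary.csv"))
    for (f in features)
      data.table::fwrite(scatter[[f]],
                         file.path(dir, paste0("shap_scatter_", f, ".csv")))
  }
  list(bar = bar, summary = summary_tab, scatter = scatter)
}

#' Population-level behavioural contrasts
#'
#' Builds the descriptive tables contrasting the resistance classes: a
#' histogram of vertical velocities pooled by class, clipped to
#' [-300, 300] mm/s, and per-strain density estimates of the segment
#' fractal dimension.
#'
#' @param fm Feature matrix with `strain` and `fractal_dimension` columns.
#' @param vy_values Optional numeric vector of per-sample vertical
#'   velocities (mm/s) with `vy_class` giving the class of each; when
#'   omitted the histogram is built from the segment-level `vy_mean`
#'   column.
#' @param vy_class Class label per element of `vy_values`.
#' @param ir_strains Strains of the resistant class.
#' @param bin_width Histogram bin width, mm/s (default 10).
#' @param dir Optional output directory (`hist_vy.csv`, `density_fd.csv`).
#' @return List with `hist_vy` (`class, bin_left, bin_right, count`) and
#'   `density_fd` (`strain, x, density`).
#' @export
population_contrasts <- function(fm, vy_values = NULL, vy_class = NULL,
                                 ir_strains = c("Banfora", "VK7"),
                                 bin_width = 10, dir = NULL) {
  if (is.null(vy_values)) {
    vy_values <- fm$vy_mean
    vy_class <- as.character(label_ir_is(fm$strain, ir_strains))
  }
  keep <- vy_values >= -300 & vy_values <= 300
  vv <- vy_values[keep]; vc <- vy_class[keep]
  lo <- floor(min(vv, 0) / bin_width) * bin_width
  hi <- ceiling(max(vv, 0) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width  # all values in a single bin
  breaks <- seq(lo, hi, by = bin_width)
  hist_vy <- do.call(rbind, lapply(sort(unique(vc)), function(cl) {
    h <- graphics::hist(vv[vc == cl], breaks = breaks, plot = FALSE)
    data.frame(class = cl, bin_left = utils::head(h$breaks, -1),
               bin_right = h$breaks[-1], count = h$counts)
  }))
  density_fd <- do.call(rbind, lapply(sort(unique(fm$strain)), function(s) {
    fd <- fm$fractal_dimension[fm$strain == s]
    if (length(fd) < 2L)
      return(data.frame(strain = s, x = fd, density = NA_real_))
    d <- stats::density(fd, from = 1, to = 2)
    data.frame(strain = s, x = d$x, density = d$y)
  }))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    data.table::fwrite(hist_vy, file.path(dir, "hist_vy.csv"))
    data.table::fwrite(density_fd, file.path(dir, "density_fd.csv"))
  }
  list(hist_vy = hist_vy, density_fd = density_fd)
}
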