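# Track-level performance metrics, per-fold aggregation, normalised
# confusion matrices and the exact Wilcoxon signed-rank test against chance.

#' Track-level performance metrics
#'
#' Computes the metric battery on whole-track predictions: accuracy,
#' balanced accuracy (mean per-class recall), ROC AUC, per-class PR AUC,
#' F1, precision and recall, Matthews correlation coefficient, Cohen's
#' kappa and log loss (probabilities clipped at 1e-15). For more than two
#' classes the threshold metrics are macro-averaged, per-class one-vs-all
#' accuracies are added, and ROC/PR AUC are reported only in the binary
#' case. A class absent from the fold leaves its rank-based metrics `NA`
#' (absent, not zero).
#'
#' @param preds Track predictions from [predict_tracks()] (columns `true`,
#'   `pred`, `prob_<class>`).
#' @return Named numeric vector of metrics.
#' @export
compute_metrics <- function(preds) {
  lev <- sub("^prob_", "", grep("^prob_", names(preds), value = TRUE))
  truth <- factor(preds$true, levels = lev)
  pred <- factor(preds$pred, levels = lev)
  probs <- as.matrix(preds[, paste0("prob_", lev), drop = FALSE])
  probs <- pmin(pmax(probs, 1e-15), 1 - 1e-15)
  cm <- table(truth, pred)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n

  recall <- diag(cm) / rowSums(cm)          # NaN when the class is absent
  precision <- diag(cm) / colSums(cm)
  f1 <- 2 * precision * recall / (precision + recall)
  f1[is.nan(f1)] <- 0
  bal_acc <- mean(recall, na.rm = TRUE)

  # Cohen's kappa
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0

  # log loss
  ll <- -mean(log(probs[cbind(seq_len(n), as.integer(truth))]))

  out <- c(accuracy = acc, balanced_accuracy = bal_acc,
           mcc = mcc_from_confusion(cm), cohen_kappa = kappa, log_loss = ll)
  if (length(lev) == 2L) {
    pos <- lev[2]
    auc <- if (length(unique(truth)) == 2L) {
      as.numeric(pROC::auc(pROC::roc(response = truth,
                                     predictor = probs[, 2],
                                     levels = lev, direction = "<",
                                     quiet = TRUE)))
    } else NA_real_
    out <- c(out, roc_auc = auc)
  }
  for (k in seq_along(lev)) {
    cl <- lev[k]
    pr_auc <- if (any(truth == cl) && any(truth != cl))
      pr_auc_binary(truth == cl, probs[, k]) else NA_real_
    out <- c(out, stats::setNames(
      c(recall[k], precision[k], f1[k], pr_auc),
      paste0(c("recall_", "precision_", "f1_", "pr_auc_"), cl)))
  }
  if (length(lev) > 2L) {
    ova <- vapply(seq_along(lev), function(k) {
      mean((truth == lev[k]) == (pred == lev[k]))
    }, numeric(1))
    out <- c(out, stats::setNames(ova, paste0("ova_accuracy_", lev)))
  }
  out
}

# Matthews correlation coefficient from a (possibly multiclass) confusion
# matrix (the multiclass generalisation reduces to the usual binary form)
mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  tk <- rowSums(cm); pk <- colSums(cm)
  num <- sum(diag(cm)) * n - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) 0 else num / den
}

# area under the precision-recall curve by step-wise integration over
# decreasing score thresholds
pr_auc_binary <- function(is_pos, score) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(is_pos[o])
  fp <- cumsum(!is_pos[o])
  # keep the last point at each distinct score
  keep <- c(diff(score[o]) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(is_pos)
  sum(diff(c(0, rec)) * prec)
}

#' Aggregate per-fold metrics
#'
#' Elementwise arithmetic mean, minimum and maximum over folds; metrics
#' absent (`NA`) in a fold are excluded from that metric's aggregation and
#' the contributing fold count is reported.
#'
#' @param fold_metrics List of named metric vectors from
#'   [compute_metrics()].
#' @return `data.frame` with `metric`, `mean`, `min`, `max`, `n_folds`.
#' @export
aggregate_folds <- function(fold_metrics) {
  stopifnot(length(fold_metrics) >= 1L)
  nms <- unique(unlist(lapply(fold_metrics, names)))
  M <- do.call(rbind, lapply(fold_metrics, function(m) unname(m[nms])))
  colnames(M) <- nms
  data.frame(metric = nms,
             mean = apply(M, 2, mean, na.rm = TRUE),
             min = apply(M, 2, min, na.rm = TRUE),
             max = apply(M, 2, max, na.rm = TRUE),
             n_folds = apply(M, 2, function(z) sum(!is.na(z))),
             row.names = NULL)
}

#' Pooled confusion matrix, normalised by true class
#'
#' Counts of (true, predicted) pairs pooled over all folds, divided by the
#' true-class row totals and expressed as percentages; every row sums to
#' 100.
#'
#' @param preds Track predictions pooled across folds (columns `true`,
#'   `pred`).
#' @return Percentage matrix (rows = true class, columns = predicted).
#' @export
pooled_confusion <- function(preds) {
  lev <- sort(unique(c(preds$true, preds$pred)))
  cm <- table(factor(preds$true, lev), factor(preds$pred, lev))
  if (nrow(preds) == 0L || any(rowSums(cm) == 0))
    stop("empty true class in the pooled predictions")
  sweep(cm, 1, rowSums(cm), "/") * 100
}

# exact null distribution of the signed-rank sum over given (mid)ranks:
# subset-sum recursion on doubled ranks so tied midranks stay integral
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  S <- sum(r2)
  f <- numeric(S + 1L)
  f[1L] <- 1
  for (rr in r2) {
    g <- f
    g[(rr + 1L):(S + 1L)] <- g[(rr + 1L):(S + 1L)] + f[1L:(S + 1L - rr)]
    f <- g / 2
  }
  w2 <- round(2 * w)
  p_ge <- sum(f[(w2 + 1L):(S + 1L)])
  p_le <- sum(f[1L:(w2 + 1L)])
  min(1, 2 * min(p_ge, p_le))
}

#' Wilcoxon signed-rank test of balanced accuracy against chance
#'
#' Two-sided exact signed-rank test on the per-fold differences between
#' balanced accuracy and the chance level (0.5 binary, 0.25 four-class),
#' with a Bonferroni correction multiplying the p-value by the number of
#' models tested. The exact null distribution is computed by a tie-aware
#' recursion over the midranks (no normal approximation up to 170 folds);
#' zero differences are dropped. With 24 uniformly positive differences the
#' corrected p-value attains its floor `6 * 2 / 2^24 = 7.15e-7`.
#'
#' @param balanced_accuracies Per-fold balanced accuracies.
#' @param chance_level Chance balanced accuracy (0.5 binary, 0.25
#'   four-class).
#' @param n_models Number of models in the correction family (default 6).
#' @return List with `statistic` (signed-rank sum W), `p`, `p_corrected`,
#'   `n_effective` and `n_models`.
#' @export
wilcoxon_vs_chance <- function(balanced_accuracies, chance_level,
                               n_models = 6L) {
  d <- balanced_accuracies - chance_level
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, p = 1, p_corrected = 1, n_effective = 0L,
                n_models = n_models))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  p <- if (length(d) <= 170L) {
    signed_rank_exact_p(w, r)
  } else {  # normal approximation with tie correction
    n <- length(d)
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    min(1, 2 * stats::pnorm(abs(w - mu) / sqrt(sig2), lower.tail = FALSE))
  }
  list(statistic = w, p = p, p_corrected = min(1, p * n_models),
       n_effective = length(d), n_models = n_models)
}
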