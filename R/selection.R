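# Statistical feature selection on the tuning partition: Mann-Whitney U
# screening under Bonferroni FWER control, followed by greedy Spearman
# decorrelation.

#' Feature-selection configuration
#'
#' @param fwer_alpha Family-wise error rate for the Mann-Whitney screen
#'   (Bonferroni-controlled), default 0.05.
#' @param spearman_rho_max Absolute Spearman correlation above which one
#'   feature of a pair is removed, default 0.85.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(fwer_alpha = 0.05, spearman_rho_max = 0.85) {
  stopifnot(fwer_alpha > 0, fwer_alpha < 1,
            spearman_rho_max > 0, spearman_rho_max < 1)
  structure(list(fwer_alpha = fwer_alpha,
                 spearman_rho_max = spearman_rho_max),
            class = "selection_config")
}

# two-sided Mann-Whitney p for one feature; exact when both groups are small
# and tie-free, normal approximation with tie correction otherwise
mw_test <- function(x, g1, g2) {
  a <- x[g1]; b <- x[g2]
  if (length(unique(c(a, b))) == 1L)
    return(c(U = length(a) * length(b) / 2, p = 1))  # constant feature
  exact <- max(length(a), length(b)) <= 50
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  c(U = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney feature screen with Bonferroni correction
#'
#' Tests every feature with the two-sided Mann-Whitney U test between the
#' two classes and keeps features with `p <= fwer_alpha / m`, where `m` is
#' the number of features tested. With more than two classes the test is
#' run pairwise over all class pairs and a feature is kept when it is
#' selected in any pair. Constant features get `p = 1` and are never
#' selected.
#'
#' @param fm Feature matrix (`data.frame`), feature columns only or with
#'   provenance columns (they are ignored via [feature_names()]).
#' @param labels Class label per row.
#' @param config A [selection_config()].
#' @return List with `selected` (feature names), and `table`
#'   (feature, U, p, selected) where multiclass p is the per-feature
#'   minimum over pairs.
#' @export
mann_whitney_select <- function(fm, labels, config = selection_config()) {
  feats <- feature_names(fm)
  labels <- as.factor(labels)
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  lev <- levels(labels)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(feats)
  res <- matrix(NA_real_, nrow = m, ncol = 2,
                dimnames = list(feats, c("U", "p")))
  sel <- logical(m)
  for (pr in pairs) {
    g1 <- labels == pr[1]; g2 <- labels == pr[2]
    for (j in seq_along(feats)) {
      r <- mw_test(fm[[feats[j]]], g1, g2)
      if (is.na(res[j, "p"]) || r["p"] < res[j, "p"]) res[j, ] <- r
      if (r["p"] <= config$fwer_alpha / m) sel[j] <- TRUE
    }
  }
  tab <- data.frame(feature = feats, U = res[, "U"], p = res[, "p"],
                    selected = sel, row.names = NULL)
  list(selected = feats[sel], table = tab)
}

#' Greedy Spearman correlation pruning
#'
#' Scans the selected features in priority order (most class-informative
#' first) and drops any feature whose absolute Spearman correlation with an
#' already-kept feature exceeds the threshold. Output order is
#' deterministic; ties in priority break by feature name.
#'
#' @param fm Feature matrix (`data.frame`).
#' @param selected Feature names surviving [mann_whitney_select()].
#' @param config A [selection_config()].
#' @param priority Numeric priority per selected feature (smaller = higher
#'   priority), typically the Mann-Whitney p-values; default keeps the
#'   given order.
#' @return List with `kept` (ordered names) and `pruned_by` (named character
#'   vector mapping each dropped feature to the kept feature that removed
#'   it).
#' @export
correlation_prune <- function(fm, selected, config = selection_config(),
                              priority = NULL) {
  if (length(selected) == 0L)
    return(list(kept = character(0), pruned_by = character(0)))
  ord <- if (is.null(priority)) seq_along(selected) else
    order(priority, selected)
  cand <- selected[ord]
  rho <- stats::cor(as.matrix(fm[, cand, drop = FALSE]), method = "spearman")
  kept <- character(0)
  pruned_by <- character(0)
  for (f in cand) {
    if (length(kept) > 0L) {
      r <- abs(rho[f, kept])
      hit <- which(r > config$spearman_rho_max)
      if (length(hit) > 0L) {
        pruned_by[f] <- kept[hit[1]]
        next
      }
    }
    kept <- c(kept, f)
  }
  list(kept = kept, pruned_by = pruned_by)
}

#' Full feature-selection step
#'
#' Mann-Whitney screening followed by correlation pruning of the survivors,
#' with pruning priority given by ascending Mann-Whitney p-value.
#'
#' @inheritParams mann_whitney_select
#' @return List with `kept`, `table` (selection report: feature, U, p,
#'   selected, pruned_by) and the intermediate `selected` set.
#' @export
select_features <- function(fm, labels, config = selection_config()) {
  mw <- mann_whitney_select(fm, labels, config)
  pr <- correlation_prune(fm, mw$selected, config,
                          priority = mw$table$p[match(mw$selected,
                                                      mw$table$feature)])
  tab <- mw$table
  tab$pruned_by <- ifelse(tab$feature %in% names(pr$pruned_by),
                          pr$pruned_by[tab$feature], "")
  list(kept = pr$kept, selected = mw$selected, table = tab)
}
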