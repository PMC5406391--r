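#' Select the significant theta/alpha features
#'
#' Returns the (channel, band) features with band theta or alpha and ANOVA
#' p at or below the Bonferroni-corrected level. If nothing passes, the
#' selection falls back (with a warning unless `quiet`) to all theta and
#' alpha features, so the downstream classifier always has inputs.
#'
#' @param stat_results Tibble from [channel_stats()] (or the per-feature
#'   part of [stats_table()]), with columns `channel`, `band`, `p` (or
#'   `rho`) and `significant`.
#' @param quiet Suppress the fallback warning? Default FALSE.
#' @return Character vector of `<channel>_<band>` feature names, with
#'   attribute `"fallback"` marking the empty-selection case.
#' @export
select_significant_features <- function(stat_results, quiet = FALSE) {
  p <- stat_results$p %||% stat_results$rho
  ta <- stat_results$band %in% c("theta", "alpha")
  sel <- ta & stat_results$significant
  fallback <- !any(sel)
  if (fallback) {
    if (!quiet) {
      warning("no theta/alpha feature passes the Bonferroni rule; ",
              "falling back to all theta and alpha features",
              call. = FALSE)
    }
    sel <- ta
  }
  out <- paste(stat_results$channel[sel], stat_results$band[sel], sep = "_")
  attr(out, "fallback") <- fallback
  out
}

# Vectorized two-group one-way ANOVA p-values across the columns of a
# matrix; agrees with one_way_anova_two_groups() column by column.
anova_p_columns <- function(X, labels) {
  X <- as.matrix(X)
  g2 <- labels == "II"
  n1 <- sum(!g2); n2 <- sum(g2); n <- n1 + n2
  m1 <- colMeans(X[!g2, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums(sweep(X[!g2, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[g2, , drop = FALSE], 2, m2)^2)
  f <- ssb / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(p)] <- 1   # degenerate zero-variance columns never selected
  p
}

# Selection + standardized PCA + tree, fit on training rows only.
# Selection uses the vectorized ANOVA (identical p-values to
# channel_stats, without the per-feature normality diagnostics).
fit_fold_model <- function(train_features, variance_target,
                           min_node_fraction, family_alpha, n_comparisons) {
  cols <- feature_columns(train_features)
  band_of <- sub("^[^_]+_", "", cols)
  ta <- cols[band_of %in% c("theta", "alpha")]
  p <- anova_p_columns(train_features[, ta, drop = FALSE],
                       train_features$condition)
  selected <- ta[p <= bonferroni_alpha(family_alpha, n_comparisons)]
  if (length(selected) == 0) selected <- ta
  X <- as.matrix(train_features[, selected, drop = FALSE])
  # Guard: a constant column cannot be standardized; drop it from the fold.
  keep <- apply(X, 2, stats::sd) > 0
  selected <- selected[keep]
  X <- X[, keep, drop = FALSE]
  pca <- fit_pca(X, variance_target)
  scores <- project_pca(pca, X)
  tree <- fit_tree(scores, train_features$condition, min_node_fraction)
  list(selected = selected, pca = pca, tree = tree)
}

predict_fold_model <- function(model, features) {
  X <- as.matrix(features[, model$selected, drop = FALSE])
  predict(model$tree, project_pca(model$pca, X))
}

#' Cross-validated PCA + decision-tree group classifier
#'
#' The multi-feature classification protocol: feature selection
#' (Bonferroni-significant theta/alpha channels), per-column
#' standardization, PCA retaining components to 95% cumulative variance,
#' and a Gini decision tree with the size-based stopping rule, evaluated
#' by `repeats` repetitions of stratified `k`-fold cross-validation.
#'
#' By default every stage — selection, standardization, PCA, tree — is
#' refit on the training folds of each iteration, so no information leaks
#' from the held-out fold. `paper_mode = TRUE` instead fits selection and
#' PCA once on the full data set and cross-validates only the tree (the
#' simpler pooled protocol some studies use; it is optimistic and kept for
#' comparison).
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param k,repeats CV controls. Defaults 10 and 10.
#' @param rng_seed Base seed for the fold assignments.
#' @param variance_target PCA retention target. Default 0.95.
#' @param min_node_fraction Tree stopping fraction. Default 0.2.
#' @param family_alpha,n_comparisons Bonferroni controls for the selection.
#' @param paper_mode Pool selection + PCA over all data? Default FALSE.
#' @return An object of class `classifier_report`: aggregate confusion
#'   counts and row-normalized matrix, `global_acc_pct`, the per-fold
#'   retained component counts, and the settings used.
#' @export
cross_validated_classify <- function(features, k = 10, repeats = 10,
                                     rng_seed = 1, variance_target = 0.95,
                                     min_node_fraction = 0.2,
                                     family_alpha = 0.05,
                                     n_comparisons = 14,
                                     paper_mode = FALSE) {
  labels <- features$condition
  pooled <- NULL
  if (paper_mode) {
    pooled <- fit_fold_model(features, variance_target, min_node_fraction,
                             family_alpha, n_comparisons)
  }
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  n_components <- integer(0)
  trees <- list()
  for (r in seq_len(repeats)) {
    folds <- stratified_kfold(labels, k, derive_seed(rng_seed, 31L, r))
    for (f in seq_len(k)) {
      test <- folds == f
      if (paper_mode) {
        model <- pooled
        scores <- project_pca(model$pca,
                              as.matrix(features[!test, model$selected]))
        model$tree <- fit_tree(scores, labels[!test], min_node_fraction)
      } else {
        model <- fit_fold_model(features[!test, , drop = FALSE],
                                variance_target, min_node_fraction,
                                family_alpha, n_comparisons)
      }
      pred <- predict_fold_model(model, features[test, , drop = FALSE])
      counts <- counts + confusion_counts(pred == "II",
                                          labels[test] == "II")
      n_components <- c(n_components, model$pca$n_retained)
      trees[[length(trees) + 1]] <- model$tree
    }
  }
  m <- confusion_metrics(counts)
  confusion <- matrix(
    c(counts[["TN"]], counts[["FP"]], counts[["FN"]], counts[["TP"]]),
    2, 2, byrow = TRUE,
    dimnames = list(truth = c("I", "II"), predicted = c("I", "II"))
  )
  structure(
    list(counts = counts,
         confusion = confusion,
         confusion_normalized = confusion / rowSums(confusion),
         global_acc_pct = 100 * m$acc,
         se_pct = 100 * m$se, sp_pct = 100 * m$sp,
         n_components = n_components,
         trees = trees,
         settings = list(k = k, repeats = repeats, rng_seed = rng_seed,
                         variance_target = variance_target,
                         min_node_fraction = min_node_fraction,
                         family_alpha = family_alpha,
                         n_comparisons = n_comparisons,
                         paper_mode = paper_mode)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %d x %d-fold CV (%s)\n",
    x$settings$repeats, x$settings$k,
    if (x$settings$paper_mode) "pooled selection + PCA" else "fully nested"))
  cat(sprintf("  retained components: %s (median %g)\n",
              paste(range(x$n_components), collapse = "-"),
              stats::median(x$n_components)))
  cat(sprintf("  global accuracy: %.2f%% (Se %.2f%%, Sp %.2f%%)\n",
              x$global_acc_pct, x$se_pct, x$sp_pct))
  cat("  confusion (rows = truth, normalized):\n")
  print(round(x$confusion_normalized, 3))
  invisible(x)
}
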