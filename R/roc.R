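#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Se = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`. Condition II (Mozart /
#' bipartite) is the positive class throughout the package.
#'
#' @param counts Named list or vector with `TP`, `FP`, `TN`, `FN`.
#' @return A list with `se`, `sp`, `acc` (proportions in `[0, 1]`).
#' @examples
#' confusion_metrics(c(TP = 3, FN = 2, TN = 4, FP = 1))
#' @export
confusion_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0) stop("sensitivity undefined: TP + FN = 0", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: TN + FP = 0", call. = FALSE)
  list(se = tp / (tp + fn),
       sp = tn / (tn + fp),
       acc = (tp + tn) / (tp + fp + tn + fn))
}

confusion_counts <- function(predicted_positive, truth_positive) {
  c(TP = sum(predicted_positive & truth_positive),
    FP = sum(predicted_positive & !truth_positive),
    TN = sum(!predicted_positive & !truth_positive),
    FN = sum(!predicted_positive & truth_positive))
}

# Apply a threshold rule: direction ">" calls condition II when the score
# exceeds the threshold; "<" when it falls below.
apply_threshold <- function(scores, threshold, direction) {
  if (direction == ">") scores > threshold else scores < threshold
}

#' ROC curve of a single feature
#'
#' Evaluates every threshold placed at the midpoints between adjacent
#' distinct score values (plus sentinels outside the score range), in both
#' class-assignment directions; the direction with the larger area under
#' the curve is retained and recorded. Condition II is the positive class.
#'
#' @param scores Numeric feature values.
#' @param labels Condition labels (`"I"` / `"II"`); both must be present.
#' @return An object of class `roc_curve`: tibble `points` with columns
#'   `threshold`, `se`, `sp` (Se non-decreasing along the list), plus
#'   fields `direction` and `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.character(labels)
  truth <- labels == "II"
  if (!any(truth) || all(truth)) {
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  }
  uq <- sort(unique(scores))
  mids <- if (length(uq) > 1) (uq[-1] + uq[-length(uq)]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)

  s_pos <- sort(scores[truth])
  s_neg <- sort(scores[!truth])
  n_pos <- length(s_pos)
  n_neg <- length(s_neg)
  # Thresholds fall strictly between score values, so "# scores <= th" from
  # findInterval equals "# scores < th" and both inequalities are exact.
  curve_for <- function(direction) {
    below_pos <- findInterval(thresholds, s_pos)
    below_neg <- findInterval(thresholds, s_neg)
    if (direction == ">") {
      se <- (n_pos - below_pos) / n_pos
      sp <- below_neg / n_neg
    } else {
      se <- below_pos / n_pos
      sp <- (n_neg - below_neg) / n_neg
    }
    ord <- order(se, -sp)
    pts <- tibble::tibble(threshold = thresholds[ord], se = se[ord],
                          sp = sp[ord])
    fpr <- 1 - pts$sp
    auc <- sum(diff(fpr) * (pts$se[-1] + pts$se[-nrow(pts)]) / 2)
    list(points = pts, auc = auc)
  }
  up <- curve_for(">")
  down <- curve_for("<")
  best <- if (up$auc >= down$auc) c(up, direction = ">") else
    c(down, direction = "<")
  structure(
    list(points = best$points, direction = best$direction, auc = best$auc,
         auc_by_direction = c(">" = up$auc, "<" = down$auc),
         degenerate = length(mids) == 0),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, direction '%s', AUC %.3f%s\n",
              nrow(x$points), x$direction, x$auc,
              if (x$degenerate) " (degenerate: tied scores)" else ""))
  invisible(x)
}

#' Select the ROC-optimal threshold
#'
#' Maximizes Youden's `J = Se + Sp - 1` over the curve's thresholds; ties
#' break toward higher specificity, then toward the lower threshold value.
#' A flat curve (all scores tied) returns the sentinel threshold, flagged
#' degenerate.
#'
#' @param roc A `roc_curve` from [roc_points()].
#' @return The chosen threshold, with attributes `j` (its Youden index),
#'   `direction` and `degenerate`.
#' @export
select_threshold <- function(roc) {
  pts <- roc$points
  if (nrow(pts) == 0) stop("empty ROC point list", call. = FALSE)
  j <- pts$se + pts$sp - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[order(-pts$sp[best],
                                           pts$threshold[best])][1]
  structure(pts$threshold[best], j = j[best], direction = roc$direction,
            degenerate = roc$degenerate)
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals members round-robin, so fold sizes
#' differ by at most one and per-fold class proportions match the global
#' proportions as closely as integer counts allow. Deterministic given the
#' seed.
#'
#' @param labels Class labels.
#' @param k Number of folds; every class must have at least `k` members.
#' @param rng_seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k, rng_seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs >= k members for stratified ", k, "-fold; ",
         "smallest class has ", min(counts), call. = FALSE)
  }
  folds <- integer(length(labels))
  with_local_seed(rng_seed, {
    offset <- 0L
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
  })
  folds
}

#' Cross-validated single-feature ROC performance
#'
#' The per-feature discrimination protocol: over `repeats` repetitions of
#' stratified `k`-fold cross-validation, a threshold (and direction) is
#' chosen on the training folds by Youden-optimal ROC scanning and applied
#' to the held-out fold; per-iteration confusion counts give Se, Sp and
#' Acc, averaged over all `k * repeats` iterations and reported as
#' percentages.
#'
#' @param feature Numeric feature values.
#' @param labels Condition labels.
#' @param k Folds per repeat. Default 10.
#' @param repeats CV repetitions. Default 10.
#' @param rng_seed Base seed; each repeat derives its own fold seed.
#' @return An object of class `cv_roc_result`: `se_pct`, `sp_pct`,
#'   `acc_pct`, and tibble `iterations` with per-iteration counts,
#'   thresholds and directions.
#' @export
evaluate_feature_cv <- function(feature, labels, k = 10, repeats = 10,
                                rng_seed = 1) {
  labels <- as.character(labels)
  iters <- vector("list", k * repeats)
  i <- 0L
  for (r in seq_len(repeats)) {
    folds <- stratified_kfold(labels, k, derive_seed(rng_seed, 23L, r))
    for (f in seq_len(k)) {
      test <- folds == f
      roc <- roc_points(feature[!test], labels[!test])
      th <- select_threshold(roc)
      pred <- apply_threshold(feature[test], as.numeric(th),
                              attr(th, "direction"))
      cc <- confusion_counts(pred, labels[test] == "II")
      m <- confusion_metrics(cc)
      i <- i + 1L
      iters[[i]] <- tibble::tibble(
        repeat_id = r, fold = f,
        TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]], FN = cc[["FN"]],
        threshold = as.numeric(th), direction = attr(th, "direction"),
        se = m$se, sp = m$sp, acc = m$acc
      )
    }
  }
  iterations <- dplyr::bind_rows(iters)
  structure(
    list(se_pct = 100 * mean(iterations$se),
         sp_pct = 100 * mean(iterations$sp),
         acc_pct = 100 * mean(iterations$acc),
         k = k, repeats = repeats,
         iterations = iterations),
    class = "cv_roc_result"
  )
}

#' @export
print.cv_roc_result <- function(x, ...) {
  cat(sprintf(
    "<cv_roc_result> %d x %d-fold CV: Se %.2f%%, Sp %.2f%%, Acc %.2f%%\n",
    x$repeats, x$k, x$se_pct, x$sp_pct, x$acc_pct))
  invisible(x)
}

#' Per-feature statistics table in the study's layout
#'
#' Combines the ANOVA significance and the cross-validated single-feature
#' ROC performance for every (channel, band) feature: one row per channel
#' per band with columns `channel`, `band`, `rho` (ANOVA p), `se_pct`,
#' `sp_pct`, `acc_pct`, `significant` — the layout of a per-band results
#' table with 14 channel rows.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param k,repeats,rng_seed CV controls (see [evaluate_feature_cv()]).
#' @param family_alpha,n_comparisons Bonferroni controls (see
#'   [channel_stats()]).
#' @return A tibble, one row per feature, carrying attribute
#'   `"bonferroni_alpha"`.
#' @export
stats_table <- function(features, k = 10, repeats = 10, rng_seed = 1,
                        family_alpha = 0.05, n_comparisons = 14) {
  stats <- channel_stats(features, family_alpha, n_comparisons)
  cols <- feature_columns(features)
  cv <- purrr::imap(cols, function(cn, i) {
    res <- evaluate_feature_cv(features[[cn]], features$condition,
                               k = k, repeats = repeats,
                               rng_seed = derive_seed(rng_seed, 29L, i))
    tibble::tibble(se_pct = res$se_pct, sp_pct = res$sp_pct,
                   acc_pct = res$acc_pct)
  }) |> dplyr::bind_rows()
  out <- dplyr::bind_cols(
    stats |> dplyr::select("channel", "band", rho = "p", "significant"),
    cv
  )
  attr(out, "bonferroni_alpha") <- attr(stats, "bonferroni_alpha")
  attr(out, "channel_stats") <- stats
  out
}
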