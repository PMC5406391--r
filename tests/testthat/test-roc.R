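test_that("confusion metrics follow their defining ratios", {
  m <- confusion_metrics(c(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unlist(m), c(se = 1, sp = 1, acc = 1))
  m2 <- confusion_metrics(c(TP = 3, FN = 2, TN = 4, FP = 1))
  expect_equal(unlist(m2), c(se = 0.6, sp = 0.8, acc = 0.7))
  expect_error(confusion_metrics(c(TP = 0, FN = 0, TN = 4, FP = 1)),
               "sensitivity")
  expect_error(confusion_metrics(c(TP = 2, FN = 1, TN = 0, FP = 0)),
               "specificity")
})

test_that("ROC curves contain the perfect-separation corner when it exists", {
  r <- roc_points(c(0.1, 0.2, 0.8, 0.9), c("I", "I", "II", "II"))
  expect_true(any(r$points$se == 1 & r$points$sp == 1))
  expect_equal(r$auc, 1)
  expect_identical(r$direction, ">")
  expect_error(roc_points(1:4, rep("I", 4)), "both classes")
})

test_that("ROC area matches an independent implementation", {
  set.seed(73)
  for (i in 1:25) {
    sc <- rnorm(30)
    lb <- sample(c("I", "II"), 30, replace = TRUE)
    if (length(unique(lb)) < 2) next
    r <- roc_points(sc, lb)
    oracle <- pROC::roc(lb, sc, levels = c("I", "II"), quiet = TRUE,
                        direction = if (r$direction == ">") "<" else ">")
    expect_equal(r$auc, as.numeric(pROC::auc(oracle)), tolerance = 1e-10)
  }
})

test_that("null scores give chance-level area", {
  set.seed(75)
  # Fixed-direction area is the chance-level quantity; the retained
  # (best-direction) area is its folded version, >= 0.5 by construction.
  aucs <- vapply(1:500, function(i) {
    roc_points(rnorm(40), rep(c("I", "II"), 20))$auc_by_direction[[">"]]
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("tied scores collapse to a degenerate chance curve", {
  r <- roc_points(rep(1, 10), rep(c("I", "II"), 5))
  expect_true(r$degenerate)
  expect_equal(r$auc, 0.5)
  th <- select_threshold(r)
  expect_true(is.infinite(as.numeric(th)))
  expect_true(attr(th, "degenerate"))
  expect_equal(attr(th, "j"), 0)
})

test_that("threshold selection maximizes Youden's J with stated tie-breaks", {
  # brute-force oracle over all midpoint cuts in both directions
  brute_best_j <- function(scores, labels) {
    uq <- sort(unique(scores))
    cuts <- c(-Inf, (uq[-1] + uq[-length(uq)]) / 2, Inf)
    truth <- labels == "II"
    best <- -Inf
    for (th in cuts) {
      for (dir in c(">", "<")) {
        pred <- if (dir == ">") scores > th else scores < th
        se <- sum(pred & truth) / sum(truth)
        sp <- sum(!pred & !truth) / sum(!truth)
        best <- max(best, se + sp - 1)
      }
    }
    best
  }

  sc <- c(0.1, 0.2, 0.8, 0.9); lb <- c("I", "I", "II", "II")
  th <- select_threshold(roc_points(sc, lb))
  expect_equal(as.numeric(th), 0.5)          # midpoint of the gap
  expect_equal(attr(th, "j"), 1)

  sc2 <- c(0.1, 0.8, 0.2, 0.9); lb2 <- c("I", "I", "II", "II")
  r2 <- roc_points(sc2, lb2)
  th2 <- select_threshold(r2)
  expect_equal(attr(th2, "j"), brute_best_j(sc2, lb2))
  expect_equal(attr(th2, "j"), 0.5)

  set.seed(77)
  for (i in 1:20) {
    sc3 <- round(rnorm(20), 1)
    lb3 <- rep(c("I", "II"), 10)
    th3 <- select_threshold(roc_points(sc3, lb3))
    expect_equal(attr(th3, "j"), brute_best_j(sc3, lb3))
  }
})

test_that("stratified folds balance classes exactly when possible", {
  lb <- rep(c("I", "II"), each = 20)
  f <- stratified_kfold(lb, 10, rng_seed = 1)
  tab <- table(f, lb)
  expect_true(all(tab == 2))
  expect_identical(f, stratified_kfold(lb, 10, rng_seed = 1))
  expect_false(identical(f, stratified_kfold(lb, 10, rng_seed = 2)))
  expect_error(stratified_kfold(lb, 40, rng_seed = 1), ">= k")
  # unbalanced classes still differ by at most one per fold
  lb2 <- c(rep("I", 13), rep("II", 21))
  f2 <- stratified_kfold(lb2, 5, rng_seed = 3)
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("cross-validated thresholding scores canonical cases exactly", {
  lb <- rep(c("I", "II"), 20)
  # perfectly separated with a wide gap
  perfect <- ifelse(lb == "II", 10, 0) + rnorm(40, sd = 0.01)
  res <- evaluate_feature_cv(perfect, lb, rng_seed = 1)
  expect_equal(res$se_pct, 100)
  expect_equal(res$sp_pct, 100)
  expect_equal(res$acc_pct, 100)

  # one flipped sample: exactly one test error per repeat
  flipped <- ifelse(lb == "II", 1, 0)
  flipped[which(lb == "II")[1]] <- 0
  res2 <- evaluate_feature_cv(flipped, lb, rng_seed = 1)
  expect_equal(res2$acc_pct, 97.5)

  # accuracy equals brute-force recomputation from stored counts
  it <- res2$iterations
  expect_equal(res2$acc_pct,
               100 * mean((it$TP + it$TN) / (it$TP + it$TN + it$FP + it$FN)))
  expect_identical(nrow(it), 100L)
})

test_that("label-independent features score near chance", {
  set.seed(79)
  accs <- vapply(1:50, function(i) {
    evaluate_feature_cv(rnorm(40), rep(c("I", "II"), 20),
                        rng_seed = i)$acc_pct
  }, 0)
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("stats_table mirrors the per-band 14-row layout", {
  fm <- cached_fm("fm4x2s_eff", function() {
    mini_cohort_features(seed = 71, effect_size = 1, duration_s = 2,
                         n_subjects = 10)
  })
  st <- stats_table(fm, k = 5, repeats = 2, rng_seed = 1)
  expect_identical(nrow(st), 56L)
  expect_named(st, c("channel", "band", "rho", "significant",
                     "se_pct", "sp_pct", "acc_pct"))
  per_band <- split(st, st$band)
  expect_length(per_band, 4)
  for (tbl in per_band) {
    expect_identical(nrow(tbl), 14L)
    expect_setequal(tbl$channel, montage_channels()$channel)
  }
  expect_true(all(st$se_pct >= 0 & st$se_pct <= 100))
  expect_true(all(st$acc_pct >= 0 & st$acc_pct <= 100))
})
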