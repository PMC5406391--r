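# Published per-channel ANOVA p-values for the theta and alpha tables,
# used as input data for the selection rule.
published_stat_results <- function() {
  ch <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
          "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  theta <- c(0.0136, 0.231, 0.00806, 3.35e-9, 2.27e-8, 0.00085, 0.11,
             1.30e-13, 1.88e-16, 1.53e-7, 6.71e-12, 2.15e-14, 0.00321,
             6.81e-6)
  alpha <- c(4.20e-11, 0.143, 1.06e-5, 7.27e-16, 2.48e-15, 2.44e-16,
             0.082, 3.45e-9, 3.04e-15, 1.25e-7, 1.25e-14, 3.39e-20,
             2.49e-12, 6.64e-12)
  tibble::tibble(
    channel = rep(ch, 2),
    band = rep(c("theta", "alpha"), each = 14),
    p = c(theta, alpha),
    significant = p <= bonferroni_alpha(0.05, 14)
  )
}

test_that("selection applied to the published tables keeps 22 features", {
  sel <- select_significant_features(published_stat_results())
  expect_length(sel, 22)   # 10 theta + 12 alpha under the stated threshold
  expect_length(grep("theta$", sel), 10)
  expect_length(grep("alpha$", sel), 12)
  expect_true("F8_theta" %in% sel)    # 0.00321 <= 0.00357, literal rule
  expect_false("F3_theta" %in% sel)   # 0.00806 fails
  expect_false(attr(sel, "fallback"))
})

test_that("empty selections fall back to all theta/alpha features", {
  null_stats <- published_stat_results()
  null_stats$p <- 0.5
  null_stats$significant <- FALSE
  expect_warning(sel <- select_significant_features(null_stats),
                 "falling back")
  expect_length(sel, 28)
  expect_true(attr(sel, "fallback"))
  expect_false(any(grepl("beta|gamma", sel)))
})

test_that("PCA retains the minimal component count for its target", {
  set.seed(81)
  f1 <- rnorm(200); f2 <- rnorm(200)
  X <- cbind(f1, f2, f1 + f2 + rnorm(200, sd = 1e-8))
  m <- fit_pca(X, variance_target = 0.999)
  expect_lte(m$n_retained, 2)
  expect_gte(sum(m$explained_fraction[1:2]), 0.999)

  iso <- matrix(rnorm(400 * 10), 400, 10)
  m2 <- fit_pca(iso)
  expect_gte(m2$n_retained, 9)   # ~10% variance each, target 95%

  m3 <- fit_pca(iso, variance_target = 1.0)
  expect_identical(m3$n_retained, 10L)

  # orthonormality and ordering
  Q <- m2$components
  expect_lt(max(abs(t(Q) %*% Q - diag(ncol(Q)))), 1e-8)
  expect_true(all(diff(m2$explained_fraction) <= 1e-12))
  # minimality: one fewer component misses the target
  cum <- cumsum(m2$explained_fraction)
  expect_lt(cum[m2$n_retained - 1], 0.95)
  expect_gte(cum[m2$n_retained], 0.95)

  expect_error(fit_pca(cbind(f1, rep(2, 200))), "constant")
})

test_that("PCA eigenvalues match the sample correlation spectrum", {
  set.seed(83)
  X <- matrix(rnorm(100 * 6), 100, 6) %*% matrix(rnorm(36), 6, 6)
  m <- fit_pca(X, variance_target = 1)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(m$explained_fraction, ev / sum(ev), tolerance = 1e-10)
})

test_that("Gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "empty")
})

test_that("the tree splits greedily at midpoints and respects stopping rules", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), ncol = 1)
  y <- rep(c("I", "II"), each = 4)
  tr <- fit_tree(x, y, min_node_fraction = 0.2)
  expect_identical(tr$root$split$column, 1L)
  expect_equal(tr$root$split$threshold, 7)         # midpoint of 4 and 10
  expect_identical(unname(predict(tr, x)), y)

  # pure input: a single leaf, not an error
  tr2 <- fit_tree(x, rep("II", 8))
  expect_identical(tr2$root$label, "II")

  # rpart cross-check on a clean 2-D separable problem
  set.seed(85)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  yy <- rep(c("I", "II"), each = 20)
  tr3 <- fit_tree(X, yy)
  rp <- rpart::rpart(factor(yy) ~ ., data.frame(X),
                     method = "class", minsplit = 8, cp = 0)
  expect_identical(unname(predict(tr3, X)),
                   as.character(predict(rp, data.frame(X), type = "class")))
})

test_that("no node smaller than the 20% rule is ever split", {
  fm <- cached_fm("fm4x2s_eff", function() {
    mini_cohort_features(seed = 71, effect_size = 1, duration_s = 2,
                         n_subjects = 10)
  })
  rep_ <- cross_validated_classify(fm, k = 5, repeats = 2, rng_seed = 9)
  min_n <- ceiling(0.2 * 16)   # training folds hold 16 of 20 rows
  for (tr in rep_$trees) {
    nodes <- tree_nodes(tr)
    internal <- nodes[!nodes$is_leaf, ]
    expect_true(all(internal$n_samples >= min_n))
    expect_true(all(internal$gini > 0))
    leaves <- nodes[nodes$is_leaf, ]
    expect_true(all(leaves$gini == 0 | leaves$n_samples < min_n |
                      leaves$gini <= 0.5))
  }
})

test_that("a strong contrast yields high cross-validated accuracy", {
  accs <- vapply(1:5, function(s) {
    fm <- mini_cohort_features(seed = 8000 + s, effect_size = 1,
                               duration_s = 4)
    cross_validated_classify(fm, rng_seed = s)$global_acc_pct
  }, 0)
  expect_true(all(accs >= 90))
})

test_that("a null cohort classifies at chance", {
  accs <- vapply(1:12, function(s) {
    fm <- mini_cohort_features(seed = 8100 + s, effect_size = 0,
                               duration_s = 2)
    suppressWarnings(
      cross_validated_classify(fm, rng_seed = s)$global_acc_pct)
  }, 0)
  expect_gte(mean(accs), 35)
  expect_lte(mean(accs), 65)
})

test_that("the report is internally consistent and deterministic", {
  fm <- cached_fm("fm4x2s_eff", function() {
    mini_cohort_features(seed = 71, effect_size = 1, duration_s = 2,
                         n_subjects = 10)
  })
  r1 <- cross_validated_classify(fm, k = 5, repeats = 2, rng_seed = 4)
  r2 <- cross_validated_classify(fm, k = 5, repeats = 2, rng_seed = 4)
  expect_identical(r1$counts, r2$counts)
  cc <- r1$counts
  expect_equal(r1$global_acc_pct,
               100 * (cc[["TP"]] + cc[["TN"]]) / sum(cc))
  expect_equal(rowSums(r1$confusion_normalized), c(I = 1, II = 1))
  expect_equal(sum(r1$counts), 2 * 20)   # every row tested once per repeat
  g <- glance(r1)
  expect_identical(g$global_acc_pct, r1$global_acc_pct)
  td <- tidy(r1)
  expect_identical(nrow(td), 4L)
  expect_equal(sum(td$count), sum(cc))
})

test_that("fold models depend only on their training rows", {
  fm <- cached_fm("fm4x2s_eff", function() {
    mini_cohort_features(seed = 71, effect_size = 1, duration_s = 2,
                         n_subjects = 10)
  })
  train_rows <- 1:16
  m1 <- phraseeg:::fit_fold_model(fm[train_rows, ], 0.95, 0.2, 0.05, 14)
  fm_perturbed <- fm
  cols <- feature_columns(fm)
  fm_perturbed[17:20, cols] <- fm_perturbed[17:20, cols] * 100
  m2 <- phraseeg:::fit_fold_model(fm_perturbed[train_rows, ], 0.95, 0.2,
                                  0.05, 14)
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$pca$components, m2$pca$components)
  expect_identical(m1$tree, m2$tree)
})

test_that("paper-mode pools selection and PCA but still cross-validates", {
  fm <- cached_fm("fm4x2s_eff", function() {
    mini_cohort_features(seed = 71, effect_size = 1, duration_s = 2,
                         n_subjects = 10)
  })
  rp <- cross_validated_classify(fm, k = 5, repeats = 2, rng_seed = 4,
                                 paper_mode = TRUE)
  expect_true(rp$settings$paper_mode)
  expect_identical(length(unique(rp$n_components)), 1L)
  expect_true(rp$global_acc_pct >= 0 && rp$global_acc_pct <= 100)
})
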