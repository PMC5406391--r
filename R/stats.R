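#' Normality and homoscedasticity checks for one feature
#'
#' Shapiro-Wilk per group and Levene's test (classical, mean-centred)
#' across groups. These are reported, not enforced: the ANOVA always runs
#' and the check p-values are carried alongside. A degenerate (constant)
#' group cannot be tested for normality and is reported as `NA`
#' (treated downstream as "not normal").
#'
#' @param feature Numeric vector.
#' @param labels Group labels (two groups), same length.
#' @return A list with `shapiro_p` (named per group) and `levene_p`.
#' @export
check_distributions <- function(feature, labels) {
  labels <- as.character(labels)
  groups <- split(feature, labels)
  if (any(lengths(groups) < 3)) {
    stop("need at least 3 samples per group", call. = FALSE)
  }
  shapiro_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, 0)
  lev <- car::leveneTest(feature ~ factor(labels), center = "mean")
  list(shapiro_p = shapiro_p, levene_p = lev[["Pr(>F)"]][1])
}

#' One-way ANOVA for two groups
#'
#' Classical between/within mean-square ratio with (1, n-2) degrees of
#' freedom, via [stats::oneway.test] with equal variances assumed. For two
#' groups the F statistic equals the square of the pooled two-sample t.
#'
#' @param feature Numeric vector.
#' @param labels Group labels; exactly two groups, each with >= 2 samples.
#' @return A list with `F` and `p`.
#' @export
one_way_anova_two_groups <- function(feature, labels) {
  labels <- as.character(labels)
  groups <- split(feature, labels)
  if (length(groups) != 2) {
    stop("expected exactly 2 groups, got ", length(groups), call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  within_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within_var == 0) {
    if (mean(groups[[1]]) == mean(groups[[2]])) {
      stop("zero within-group variance with equal means: F undefined",
           call. = FALSE)
    }
    return(list(F = Inf, p = 0))
  }
  ft <- stats::oneway.test(feature ~ factor(labels), var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Bonferroni-corrected significance level
#'
#' Familywise level divided by the number of comparisons; with the study's
#' 14 channels, `0.05 / 14 = 0.00357` (3 s.f.).
#'
#' @param family_alpha Familywise level in (0, 1). Default 0.05.
#' @param n_channels Number of comparisons. Default 14.
#' @return The per-comparison level.
#' @examples
#' bonferroni_alpha(0.05, 14)
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_channels = 14) {
  stopifnot(family_alpha > 0, family_alpha < 1, n_channels >= 1)
  family_alpha / n_channels
}

#' Per-feature group statistics over a feature matrix
#'
#' For every (channel, band) feature: Shapiro-Wilk p per condition,
#' Levene p, the two-group ANOVA F and p, and the significance flag under
#' the Bonferroni-corrected level (by default 0.05 / 14, dividing by
#' channels, with `n_comparisons` available for a stricter correction).
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param family_alpha Familywise level. Default 0.05.
#' @param n_comparisons Divisor of the correction. Default 14 (channels).
#' @return A tibble with one row per feature: `channel`, `band`,
#'   `shapiro_p_I`, `shapiro_p_II`, `levene_p`, `F`, `p`, `significant`.
#' @export
channel_stats <- function(features, family_alpha = 0.05,
                          n_comparisons = 14) {
  alpha <- bonferroni_alpha(family_alpha, n_comparisons)
  cols <- feature_columns(features)
  labels <- features$condition
  res <- purrr::map(cols, function(cn) {
    x <- features[[cn]]
    chk <- check_distributions(x, labels)
    an <- one_way_anova_two_groups(x, labels)
    parts <- strsplit(cn, "_")[[1]]
    tibble::tibble(
      channel = parts[1], band = parts[2],
      shapiro_p_I = unname(chk$shapiro_p["I"]),
      shapiro_p_II = unname(chk$shapiro_p["II"]),
      levene_p = chk$levene_p,
      F = an$F, p = an$p,
      significant = an$p <= alpha
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "bonferroni_alpha") <- alpha
  out
}
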