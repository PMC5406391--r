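#' Tidy a classifier report
#'
#' One row per confusion-matrix cell with raw counts and row-normalized
#' proportions.
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with `truth`, `predicted`, `count`, `prop`.
#' @export
tidy.classifier_report <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(df) <- c("truth", "predicted", "count")
  out <- tibble::as_tibble(df)
  out$prop <- out$count / stats::ave(out$count, out$truth, FUN = sum)
  out
}

#' One-row summary of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with `global_acc_pct`, `se_pct`, `sp_pct`,
#'   `n_components_median`, `k`, `repeats`, `paper_mode`.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(
    global_acc_pct = x$global_acc_pct,
    se_pct = x$se_pct,
    sp_pct = x$sp_pct,
    n_components_median = stats::median(x$n_components),
    k = x$settings$k,
    repeats = x$settings$repeats,
    paper_mode = x$settings$paper_mode
  )
}

#' Tidy a single-feature CV result
#'
#' @param x A `cv_roc_result`.
#' @param ... Unused.
#' @return The per-iteration tibble (repeat, fold, confusion counts,
#'   threshold, direction, Se/Sp/Acc).
#' @export
tidy.cv_roc_result <- function(x, ...) x$iterations

#' One-row summary of a single-feature CV result
#'
#' @param x A `cv_roc_result`.
#' @param ... Unused.
#' @return A tibble with `se_pct`, `sp_pct`, `acc_pct`, `k`, `repeats`.
#' @export
glance.cv_roc_result <- function(x, ...) {
  tibble::tibble(se_pct = x$se_pct, sp_pct = x$sp_pct,
                 acc_pct = x$acc_pct, k = x$k, repeats = x$repeats)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL
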