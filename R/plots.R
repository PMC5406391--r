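#' Plot a topographic group-average power summary
#'
#' Head-circle view of per-channel group-average spectral power:
#' IDW-interpolated surface with electrode markers, one panel per group.
#'
#' @param object An `eeg_topo` tibble from [summarize_topography()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_topo <- function(object, ...) {
  surf <- dplyr::bind_rows(
    interpolate_topography(object, "group_I") |>
      dplyr::mutate(group = "Group I (rondo)"),
    interpolate_topography(object, "group_II") |>
      dplyr::mutate(group = "Group II (bipartite)")
  )
  pts <- tidyr::pivot_longer(object, c("group_I", "group_II"),
                             names_to = "group", values_to = "power") |>
    dplyr::mutate(group = ifelse(.data$group == "group_I",
                                 "Group I (rondo)", "Group II (bipartite)"))
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 200),
                         x = cos(.data$theta), y = sin(.data$theta))
  ggplot2::ggplot(surf, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = circ, linewidth = 0.3) +
    ggplot2::geom_point(data = pts, shape = 21, fill = "white", size = 2) +
    ggplot2::geom_text(data = pts, ggplot2::aes(label = .data$channel),
                       nudge_y = 0.09, size = 2.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_viridis_c(name = "mean SP") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Group-average %s power", object$band[1]))
}

#' Plot a classifier report's confusion matrix
#'
#' Row-normalized confusion matrix (rows = truth) with raw counts
#' annotated.
#'
#' @param object A `classifier_report` from [cross_validated_classify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  df$prop <- as.vector(t(apply(object$confusion, 1,
                               function(r) r / sum(r))))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%\n(n=%d)", 100 * .data$prop, .data$count))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "row prop.") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "Predicted group", y = "True group",
      title = sprintf("Cross-validated confusion matrix (accuracy %.1f%%)",
                      object$global_acc_pct))
}

#' Plot per-feature cross-validated accuracy by channel and band
#'
#' Dot plot of the single-feature CV accuracies in a [stats_table()],
#' with significant features highlighted.
#'
#' @param stats_tbl A tibble from [stats_table()].
#' @return A ggplot object.
#' @export
plot_feature_performance <- function(stats_tbl) {
  df <- stats_tbl |>
    dplyr::mutate(
      channel = factor(.data$channel, montage_channels()$channel),
      band = factor(.data$band, band_names()))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$acc_pct,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::facet_wrap(~band, ncol = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
      name = "Bonferroni-significant") +
    ggplot2::labs(x = NULL, y = "CV accuracy (%)",
                  title = "Single-feature discrimination by channel and band") +
    ggplot2::theme_minimal()
}
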