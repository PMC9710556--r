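#' Plot a purity-divergence k-sweep
#'
#' Score (nats) against neighbourhood size on a log-2 x axis; points are
#' annotated with permutation p-values when present.
#'
#' @param object A [k_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_result <- function(object, ...) {
  df <- object$score_by_k
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(trans = "log2", breaks = df$k) +
    ggplot2::labs(x = "neighbourhood size k", y = "purity divergence (nats)",
                  title = sprintf("k-NN purity divergence (m = %d, n = %d)",
                                  object$m, object$n)) +
    ggplot2::theme_minimal()
  if (any(!is.na(df$p_value))) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$p_value), "",
                                  sprintf("p=%.3g", .data$p_value))),
      vjust = -0.8, size = 3)
  }
  p
}

#' Shape-versus-spatial divergence summary scatter
#'
#' One point per organelle channel: log shape divergence (at the reference
#' k) against log spatial KL divergence. Channels in the lower-left corner
#' reproduce both the shape and the spatial distribution of the real
#' objects well.
#'
#' @param object An [run_full_evaluation()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- object$per_organelle
  df <- df[!is.na(df$shape_divergence) & !is.na(df$spatial_kl), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = log10(pmax(.data$shape_divergence, 1e-6)),
                                   y = log10(pmax(.data$spatial_kl, 1e-6)),
                                   label = .data$organelle)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(x = "log10 shape divergence", y = "log10 spatial KL divergence",
                  title = "Shape vs spatial divergence by organelle") +
    ggplot2::theme_minimal()
}

#' Radial distribution of normalized object positions
#'
#' Histogram of fractional radii (0 = nuclear centroid, 1 = cell membrane),
#' optionally split by a grouping column.
#'
#' @param positions Tibble from [normalize_objects()]; an optional `group`
#'   column colours the histogram.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(positions, bins = 20) {
  aes <- if ("group" %in% names(positions)) {
    ggplot2::aes(x = .data$r, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$r)
  }
  ggplot2::ggplot(positions, aes) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::labs(x = "fractional radius r", y = "objects") +
    ggplot2::theme_minimal()
}
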