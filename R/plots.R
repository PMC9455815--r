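#' Boxplots of per-unit metric distributions
#'
#' @param object A `validation_report`.
#' @param metrics Metric columns to show (default the full panel).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object,
                                       metrics = c(
                                         "auroc", "auprc", "bedroc",
                                         "p_at_k", "r_at_k"
                                       ), ...) {
  df <- tidy(object) |>
    dplyr::select(dplyr::any_of(c("unit", metrics))) |>
    tidyr::pivot_longer(-"unit", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = NULL, y = "metric value",
      title = object$predictor,
      subtitle = sprintf("per-%s distribution", object$unit)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot scaffold/target diversity against result-list length
#'
#' @param curves Output of [diversity_curves()].
#' @return A ggplot object.
#' @export
plot_diversity_curves <- function(curves) {
  df <- curves |>
    dplyr::select("L", "n_unique_scaffolds", "n_novel_scaffolds", "n_unique_targets") |>
    tidyr::pivot_longer(-"L", names_to = "series", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$count, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "top-L predictions", y = "unique count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an alpha-sweep summary
#'
#' @param sweep Output of [alpha_sweep()].
#' @param metric Summary column to plot (default `"auprc_median"`).
#' @return A ggplot object.
#' @export
plot_alpha_sweep <- function(sweep, metric = "auprc_median") {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$alpha, y = .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "similarity cutoff", y = metric) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding
#'
#' @param coords Output of [embed_2d()].
#' @param colour Optional grouping vector (e.g. scaffold novelty).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, colour = NULL) {
  df <- tibble(
    dim1 = coords[, 1], dim2 = coords[, 2],
    group = colour %||% "all"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}
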