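#' Plot sensitivity and precision against planted read depth
#'
#' @param depth_table Tibble from [depth_titration()] (columns `depth`,
#'   `sensitivity`, `precision`; extra grouping columns such as `seed` are
#'   averaged over).
#' @return A ggplot.
#' @export
plot_detection_performance <- function(depth_table) {
  long <- depth_table |>
    dplyr::group_by(.data$depth) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity, na.rm = TRUE),
                     precision = mean(.data$precision, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("sensitivity", "precision"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "fragments per circle", y = NULL, colour = NULL,
                  title = "circRNA detection performance vs read depth") +
    ggplot2::theme_minimal()
}

#' Boxplot of RNase-R fold-change enrichment by feature class
#'
#' @param x A `circ_enrichment` object from [enrichment_fold_change()].
#' @return A ggplot.
#' @export
plot_enrichment_fold_change <- function(x) {
  ggplot2::ggplot(x$fold_changes,
                  ggplot2::aes(x = .data$class, y = .data$fold_change,
                               fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "FPKM fold change (treated / untreated)",
                  title = "RNase-R enrichment by feature class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circ_enrichment <- function(object, ...) {
  plot_enrichment_fold_change(object)
}

#' ECDF of miRNA seed-match density by sequence class
#'
#' @param density_table Tibble from [seed_density()] with a `class` column.
#' @return A ggplot.
#' @export
plot_seed_density <- function(density_table) {
  stopifnot("class" %in% names(density_table))
  ggplot2::ggplot(density_table,
                  ggplot2::aes(x = .data$density, colour = .data$class)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "seed matches per kb", y = "ECDF", colour = NULL,
                  title = "miRNA seed-match density by sequence class") +
    ggplot2::theme_minimal()
}
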