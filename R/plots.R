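#' Stacked bar chart of pattern frequencies
#'
#' Visualises a [tabulate_patterns()] table: per-group stacked bars of the
#' seven exact lineage patterns.
#'
#' @param freq A frequency table from [tabulate_patterns()].
#' @param group Name of the grouping column to place on the x axis
#'   (default the first column).
#' @return A ggplot object.
#' @export
plot_pattern_frequencies <- function(freq, group = names(freq)[1]) {
  dat <- dplyr::filter(freq, .data$measure == "pattern")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data[[group]]),
                                    y = .data$prop, fill = .data$level)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = group, y = "Frequency", fill = "Pattern") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of within-year beekeeper consistency
#'
#' @param summary_tbl Output of [consistency_summary()].
#' @return A ggplot object.
#' @export
plot_consistency <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = factor(.data$year), y = .data$prop,
                               fill = .data$classification)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "Year", y = "Proportion of multi-sample beekeepers",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
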