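#' Classify within-year beekeeper consistency
#'
#' Beekeepers who provided two or more honey samples in the same
#' production year are classified by whether all their samples share one
#' exact lineage pattern: `"all only-C"` when every sample is exactly
#' {C}, `"uniform <pattern>"` when every sample shares some other single
#' pattern, and `"different patterns"` when at least two distinct exact
#' patterns occur. Consistency means identical exact patterns, not merely
#' overlapping lineages. Beekeeper-years with a single sample are not
#' classified.
#'
#' @param samples Honey sample tibble.
#' @param collapse_uniform Collapse all non-C uniform categories into one
#'   `"uniform other"` label? Default FALSE (one label per shared
#'   pattern).
#' @return Tibble with one row per qualifying beekeeper-year:
#'   `beekeeper_id`, `year`, `n_samples`, `n_patterns`, `classification`.
#' @export
classify_consistency <- function(samples, collapse_uniform = FALSE) {
  out <- samples |>
    dplyr::group_by(.data$beekeeper_id, .data$year) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_patterns = dplyr::n_distinct(.data$pattern),
      shared = dplyr::first(.data$pattern),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_samples >= 2) |>
    dplyr::mutate(classification = dplyr::case_when(
      .data$n_patterns > 1 ~ "different patterns",
      .data$shared == "C" ~ "all only-C",
      TRUE ~ paste("uniform", .data$shared)
    )) |>
    dplyr::select(-"shared")
  if (collapse_uniform) {
    out <- dplyr::mutate(out, classification = ifelse(
      startsWith(.data$classification, "uniform"), "uniform other",
      .data$classification))
  }
  out
}

#' Per-year consistency proportions
#'
#' Summarises [classify_consistency()] by production year: the proportion
#' of multi-sample beekeepers in each classification. Proportions within
#' a year sum to 1; the denominator is the number of beekeeper-years with
#' at least two samples.
#'
#' @inheritParams classify_consistency
#' @return Tibble with `year`, `classification`, `n_beekeepers`,
#'   `n_total`, `prop`, `pct`.
#' @export
consistency_summary <- function(samples, collapse_uniform = FALSE) {
  classify_consistency(samples, collapse_uniform = collapse_uniform) |>
    dplyr::count(.data$year, .data$classification, name = "n_beekeepers") |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(n_total = sum(.data$n_beekeepers),
                  prop = .data$n_beekeepers / .data$n_total,
                  pct = report_pct(.data$prop)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$classification)
}
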