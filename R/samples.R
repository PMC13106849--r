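#' Italian region to macro-region lookup
#'
#' The eight Northern regions follow the set used for the longitudinal
#' analyses (Piedmont, Valle d'Aosta, Liguria, Lombardy, Trentino-Alto
#' Adige, Veneto, Friuli-Venezia Giulia, Emilia-Romagna); Sicily and
#' Sardinia are their own macro-regions; the Central/South split of the
#' remaining ten regions follows the standard Italian statistical
#' convention. The mapping ships as an editable CSV in
#' `system.file("extdata", "italy_regions.csv", package = "honeybiogeo")`.
#'
#' @param path Optional path to an alternative region map CSV with columns
#'   `region` and `macro_region`.
#' @return A tibble with columns `region` and `macro_region`.
#' @export
italy_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "italy_regions.csv", package = "honeybiogeo")
  }
  map <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("region", "macro_region") %in% names(map))) {
    stop("region map must have columns 'region' and 'macro_region'", call. = FALSE)
  }
  if (anyDuplicated(map$region)) {
    stop("region map assigns some region to more than one macro-region", call. = FALSE)
  }
  tibble::as_tibble(map)
}

#' Macro-region labels
#' @return Character vector of the five macro-regions.
#' @export
macro_region_levels <- function() {
  c("North", "Central", "South", "Sicily", "Sardinia")
}

required_sample_columns <- function() {
  c("sample_id", "beekeeper_id", "year", "latitude", "longitude",
    "region", "pattern")
}

#' Read a honey sample table
#'
#' Reads a delimited text file (CSV or TSV, autodetected from the file
#' extension) with one row per honey sample and columns `sample_id`,
#' `beekeeper_id`, `year`, `latitude`, `longitude`, `region`, `pattern`
#' and optionally `macro_region` (derived from the region map when
#' absent). Pattern tokens are canonicalised with [parse_pattern()];
#' rows with no amplified lineage are rejected.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param region_map Region to macro-region lookup, default
#'   [italy_regions()]. Ignored when the file carries its own
#'   `macro_region` column.
#' @return A validated tibble of honey samples.
#' @export
read_samples <- function(path, region_map = italy_regions()) {
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext %in% c("tsv", "txt", "tab")) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(
    year = readr::col_integer(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  as_honey_samples(raw, region_map = region_map)
}

#' Validate and canonicalise a honey sample table
#'
#' @param x A data frame with the columns listed under [read_samples()].
#' @param region_map Region lookup used to derive `macro_region` if missing.
#' @return A tibble with canonical patterns and a `macro_region` column.
#' @export
as_honey_samples <- function(x, region_map = italy_regions()) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(required_sample_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$pattern <- parse_pattern(x$pattern, context = paste0("sample ", x$sample_id))
  if (!"macro_region" %in% names(x)) {
    x <- dplyr::left_join(x, region_map, by = "region")
    if (anyNA(x$macro_region)) {
      bad <- unique(x$region[is.na(x$macro_region)])
      stop("region(s) not present in the region map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    dup <- dplyr::distinct(x, .data$region, .data$macro_region)
    if (anyDuplicated(dup$region)) {
      stop("some region maps to more than one macro_region", call. = FALSE)
    }
  }
  out_of_box <- !is.na(x$latitude) & !is.na(x$longitude) &
    (x$latitude < 35 | x$latitude > 48 | x$longitude < 6 | x$longitude > 19)
  if (any(out_of_box)) {
    warning(sum(out_of_box), " sample(s) have coordinates outside the ",
            "Italian bounding box (lat 35-48, lon 6-19)", call. = FALSE)
  }
  x
}

#' Write a honey sample table
#'
#' @param samples Honey sample tibble.
#' @param path Output path; `.tsv` extension writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) {
    readr::write_tsv(samples, path, progress = FALSE)
  } else {
    readr::write_csv(samples, path, progress = FALSE)
  }
  invisible(path)
}

#' Reduce to unique samples: one per beekeeper and year
#'
#' Beekeepers may submit several ("redundant") honey samples in the same
#' production year; the unique-sample view randomly retains exactly one
#' sample per (beekeeper, year) pair. Samples from distinct years of the
#' same beekeeper are all retained. The draw is uniform over the redundant
#' set and fully reproducible given `seed`; the output is sorted by
#' beekeeper and year, so the operation is idempotent.
#'
#' @param samples Honey sample tibble.
#' @param seed Integer RNG seed for the random retention.
#' @return Tibble with exactly one row per (beekeeper_id, year).
#' @export
dedup_unique <- function(samples, seed = 1L) {
  stopifnot(all(c("beekeeper_id", "year") %in% names(samples)))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  samples |>
    dplyr::arrange(.data$beekeeper_id, .data$year, .data$sample_id) |>
    dplyr::group_by(.data$beekeeper_id, .data$year) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$beekeeper_id, .data$year)
}

#' Assign the reporting time window for a production year
#'
#' Samples produced before 2018 are grouped into three historical windows
#' (1986-1999, 2000-2009, 2010-2017); samples from 2018-2023 are labelled
#' with their literal year.
#'
#' @param year Integer vector of production years in 1986..2023.
#' @return Character vector of window labels.
#' @export
#' @examples
#' assign_time_window(c(1999, 2010, 2021))
assign_time_window <- function(year) {
  year <- as.integer(year)
  if (any(is.na(year)) || any(year < 1986 | year > 2023)) {
    stop("year out of the supported range 1986-2023", call. = FALSE)
  }
  dplyr::case_when(
    year <= 1999 ~ "1986-1999",
    year <= 2009 ~ "2000-2009",
    year <= 2017 ~ "2010-2017",
    TRUE ~ as.character(year)
  )
}

#' Tabulate lineage pattern frequencies by arbitrary grouping
#'
#' For each observed group, counts and relative frequencies are reported
#' for the seven exact patterns and for the six derived binary codings
#' (`contains-A`, ..., `only-M`). Percentages follow the one-decimal
#' half-up reporting convention, with two decimals for sub-1% values.
#' Groups with zero samples are omitted, not zero-filled.
#'
#' @param samples Honey sample tibble.
#' @param group_by Character vector of grouping columns (e.g. `"year"`,
#'   `c("macro_region", "year")`, or `character(0)` for a single overall
#'   group). `"time_window"` may be requested even if absent: it is derived
#'   with [assign_time_window()].
#' @return A tibble with the grouping columns plus `measure` ("pattern" or
#'   "coding"), `level`, `n_total`, `n`, `prop` and `pct`.
#' @export
tabulate_patterns <- function(samples, group_by = "year") {
  if (nrow(samples) == 0) stop("empty sample collection", call. = FALSE)
  if ("time_window" %in% group_by && !"time_window" %in% names(samples)) {
    samples <- dplyr::mutate(samples, time_window = assign_time_window(.data$year))
  }
  unknown <- setdiff(group_by, names(samples))
  if (length(unknown) > 0) {
    stop("unknown grouping key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  grouped <- dplyr::group_by(samples, dplyr::across(dplyr::all_of(group_by)))

  pat <- grouped |>
    dplyr::summarise(
      n_total = dplyr::n(),
      counts = list(table(factor(.data$pattern, levels = pattern_levels()))),
      .groups = "drop"
    ) |>
    dplyr::mutate(tab = purrr::map(.data$counts, function(tb) {
      tibble::tibble(level = names(tb), n = as.integer(tb))
    })) |>
    dplyr::select(-"counts") |>
    tidyr::unnest("tab") |>
    dplyr::filter(.data$n > 0) |>
    dplyr::mutate(measure = "pattern")

  cod <- grouped |>
    dplyr::summarise(
      n_total = dplyr::n(),
      patterns = list(.data$pattern),
      .groups = "drop"
    ) |>
    dplyr::mutate(tab = purrr::map(.data$patterns, function(p) {
      purrr::map_dfr(coding_levels(), function(cd) {
        tibble::tibble(level = cd, n = sum(apply_coding(p, cd)))
      })
    })) |>
    dplyr::select(-"patterns") |>
    tidyr::unnest("tab") |>
    dplyr::mutate(measure = "coding")

  dplyr::bind_rows(pat, cod) |>
    dplyr::mutate(
      prop = .data$n / .data$n_total,
      pct = report_pct(.data$prop)
    ) |>
    dplyr::select(dplyr::all_of(group_by), "measure", "level",
                  "n_total", "n", "prop", "pct") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_by, "measure", "level"))))
}

#' Grid-cell sample density export
#'
#' Counts samples per square grid cell (default 0.25 degrees) for each
#' binary coding, as a plain-text replacement for GIS density maps.
#'
#' @param samples Honey sample tibble.
#' @param cell Cell size in decimal degrees.
#' @param codings Codings to count, default all six.
#' @return Tibble with `lat_bin`, `lon_bin`, `coding`, `n`.
#' @export
grid_density <- function(samples, cell = 0.25, codings = coding_levels()) {
  base <- samples |>
    dplyr::mutate(
      lat_bin = floor(.data$latitude / cell) * cell,
      lon_bin = floor(.data$longitude / cell) * cell
    )
  purrr::map_dfr(codings, function(cd) {
    base |>
      dplyr::mutate(y = apply_coding(.data$pattern, cd)) |>
      dplyr::filter(.data$y == 1L) |>
      dplyr::count(.data$lat_bin, .data$lon_bin, name = "n") |>
      dplyr::mutate(coding = cd, .before = "n")
  })
}
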