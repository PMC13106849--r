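# Build a small honey sample tibble in code.
make_samples <- function(beekeeper_id, year, pattern,
                         macro_region = "North",
                         latitude = 45, longitude = 9,
                         region = NULL) {
  n <- max(length(beekeeper_id), length(year), length(pattern))
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    beekeeper_id = rep_len(beekeeper_id, n),
    year = rep_len(as.integer(year), n),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    region = rep_len(region %||% paste0(macro_region, "-1"), n),
    macro_region = rep_len(macro_region, n),
    pattern = parse_pattern(rep_len(pattern, n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random sample table with known redundancy structure.
random_samples <- function(n_beekeepers = 30, years = 2018:2023, seed = 1) {
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_beekeepers), function(i) {
      yrs <- sort(sample(years, sample(seq_along(years), 1)))
      purrr::map_dfr(yrs, function(yy) {
        k <- sample(1:4, 1)
        tibble::tibble(beekeeper_id = sprintf("B%03d", i), year = yy,
                       pattern = sample(pattern_levels(), k, replace = TRUE),
                       macro_region = sample(macro_region_levels(), 1))
      })
    })
    rows |>
      dplyr::mutate(sample_id = sprintf("S%04d", dplyr::row_number()),
                    latitude = runif(dplyr::n(), 37, 46),
                    longitude = runif(dplyr::n(), 7, 17),
                    region = paste0(macro_region, "-1"))
  })
}

# A small fast generator configuration used across tests.
tiny_config <- function(seed = 1, n_beekeepers = 150, ...) {
  sim_config(n_beekeepers = n_beekeepers, seed = seed, ...)
}
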