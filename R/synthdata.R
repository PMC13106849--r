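#' Synthetic region grid
#'
#' Twenty synthetic administrative regions grouped into the five
#' macro-regions (North, Central, South, Sicily, Sardinia), each defined
#' as a latitude/longitude box roughly shadowing the Italian geography:
#' a northern band, a central and a southern peninsular band, and two
#' island boxes. `weight` is the relative sampling intensity used when
#' placing beekeepers; the defaults put roughly half the beekeepers in
#' the North, mirroring the density of managed apiaries.
#'
#' @return Tibble with `region`, `macro_region`, `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`, `weight`.
#' @export
synthetic_region_grid <- function() {
  box <- function(macro, i, lat_min, lat_max, lon_min, lon_max, weight) {
    tibble::tibble(region = sprintf("%s-%d", macro, i), macro_region = macro,
                   lat_min = lat_min, lat_max = lat_max,
                   lon_min = lon_min, lon_max = lon_max, weight = weight)
  }
  north <- purrr::map_dfr(1:8, function(i) {
    lon0 <- 7 + (i - 1) %% 4 * 1.625
    lat0 <- if (i <= 4) 44.0 else 45.5
    box("North", i, lat0, lat0 + 1.5, lon0, lon0 + 1.625, 0.45 / 8)
  })
  central <- purrr::map_dfr(1:4, function(i) {
    lon0 <- 10 + (i - 1) * 1.0
    box("Central", i, 41.5, 44.0, lon0, lon0 + 1.0, 0.20 / 4)
  })
  south <- purrr::map_dfr(1:5, function(i) {
    lon0 <- 13 + (i - 1) * 1.0
    box("South", i, 38.0, 41.5, lon0, lon0 + 1.0, 0.20 / 5)
  })
  sicily <- purrr::map_dfr(1:2, function(i) {
    box("Sicily", i, 36.5, 38.0, 12.5 + (i - 1) * 1.5, 14.0 + (i - 1) * 1.5, 0.08 / 2)
  })
  sardinia <- box("Sardinia", 1, 38.9, 41.3, 8.0, 9.8, 0.07)
  dplyr::bind_rows(north, central, south, sicily, sardinia)
}

#' Configuration for the synthetic honey-sampling generator
#'
#' Defines the study conditions the generator emulates: beekeepers with
#' fixed locations sampled over several production years, colony-level
#' lineage frequencies following logistic clines in latitude and
#' longitude with yearly drift, honey patterns formed as the union of
#' lineages over a pool of colonies, and a redundancy law for multiple
#' same-year samples per beekeeper.
#'
#' Colony-level frequencies use a multinomial-logit surface: for lineage
#' L, `eta_L = alpha_L + beta_lat_L * (lat - lat0) + beta_lon_L * (lon -
#' lon0) + gamma_L * drift_mult(macro) * (year - year0)` plus an additive
#' per-macro-region island offset; `(p_A, p_C, p_M)` is the softmax of the
#' three linear predictors. C is the reference lineage (all coefficients
#' zero), so `alpha_A`/`alpha_M` are approximately log frequency ratios at
#' the grid centroid. Defaults emulate a C-dominated peninsula where A and
#' M rise southward and westward, a strongly A-shifted Sicily, and a
#' Central+South-only drift toward higher A/M frequencies.
#'
#' @param n_beekeepers Number of beekeepers; the default, with the default
#'   participation and redundancy laws, yields roughly 4,000 samples over
#'   six years, the scale of a national honey survey.
#' @param years Integer vector of production years.
#' @param coefficients Data frame with columns `lineage`, `alpha`,
#'   `beta_lat`, `beta_lon`, `gamma` (logit-scale cline coefficients).
#' @param centre Named numeric: centring constants `lat0`, `lon0`
#'   (`year0` is always the first simulated year).
#' @param island_offsets Named list per macro-region of named numeric
#'   additive offsets on the lineage linear predictors, e.g.
#'   `list(Sicily = c(A = 7))`.
#' @param drift_mult Named numeric multiplier on the yearly drift per
#'   macro-region (1 = full drift, 0 = stable).
#' @param pool_k Integer length-2: discrete-uniform pool-size bounds
#'   (colonies contributing to one honey sample).
#' @param detect_d Per-colony detection probability in (0, 1].
#' @param redundancy_law Probabilities over 1..9 samples per
#'   beekeeper-year; default mean about 1.4, matching a survey where most
#'   beekeepers send a single jar.
#' @param participation_law Probabilities over the number of active years
#'   per beekeeper (length `length(years)`).
#' @param beekeeper_sd Standard deviation of an optional beekeeper-level
#'   random intercept on the A and M linear predictors (apiary
#'   clustering); default 0 (off).
#' @param region_grid Region grid tibble, see [synthetic_region_grid()].
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_beekeepers = 1300,
                       years = 2018:2023,
                       coefficients = default_cline_coefficients(),
                       centre = c(lat0 = 42, lon0 = 12),
                       island_offsets = list(Sicily = c(A = 7)),
                       drift_mult = c(North = 0, Central = 1, South = 1,
                                      Sicily = 0, Sardinia = 0),
                       pool_k = c(10L, 30L),
                       detect_d = 1,
                       redundancy_law = c(0.78, 0.12, 0.05, 0.025, 0.012,
                                          0.006, 0.004, 0.002, 0.001),
                       participation_law = c(0.45, 0.20, 0.12, 0.10, 0.08, 0.05),
                       beekeeper_sd = 0,
                       region_grid = synthetic_region_grid(),
                       seed = 1L) {
  stopifnot(n_beekeepers >= 0, length(years) >= 1,
            pool_k[1] >= 1, pool_k[2] >= pool_k[1],
            detect_d > 0, detect_d <= 1,
            abs(sum(redundancy_law) - 1) < 1e-8,
            length(participation_law) == length(years),
            abs(sum(participation_law) - 1) < 1e-8,
            beekeeper_sd >= 0)
  stopifnot(all(c("lineage", "alpha", "beta_lat", "beta_lon", "gamma") %in%
                  names(coefficients)),
            setequal(coefficients$lineage, c("A", "C", "M")))
  structure(list(
    n_beekeepers = as.integer(n_beekeepers),
    years = as.integer(years),
    coefficients = tibble::as_tibble(coefficients),
    centre = centre,
    island_offsets = island_offsets,
    drift_mult = drift_mult,
    pool_k = as.integer(pool_k),
    detect_d = detect_d,
    redundancy_law = redundancy_law,
    participation_law = participation_law,
    beekeeper_sd = beekeeper_sd,
    region_grid = tibble::as_tibble(region_grid),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default colony-level cline coefficients
#'
#' Logit-scale coefficients calibrated so that, through the pooled-union
#' sampling with 10-30 colonies, the synthetic contains-A and contains-M
#' sample frequencies run from roughly 10-14% in the North to 25-38% in
#' the South while only-C declines, the structure of the observed Italian
#' honey data. Latitude slopes are negative (frequencies rise southward,
#' with latitude in north-positive decimal degrees) and longitude slopes
#' negative (frequencies fall eastward across the North).
#'
#' @return Tibble with columns `lineage`, `alpha`, `beta_lat`, `beta_lon`,
#'   `gamma`.
#' @export
default_cline_coefficients <- function() {
  tibble::tibble(
    lineage  = c("A", "C", "M"),
    alpha    = c(-4.65, 0, -4.35),
    beta_lat = c(-0.16, 0, -0.17),
    beta_lon = c(-0.06, 0, -0.06),
    gamma    = c(0.15, 0, 0.15)
  )
}

# sample() treats a scalar first argument as 1:n; this always samples
# from the given vector's elements.
resample <- function(vals, n, prob = NULL) {
  vals[sample.int(length(vals), n, replace = TRUE, prob = prob)]
}

# Macro-region lookup from coordinates via the config's region grid.
locate_macro <- function(config, latitude, longitude) {
  grid <- config$region_grid
  out <- rep(NA_character_, length(latitude))
  for (i in seq_len(nrow(grid))) {
    hit <- is.na(out) &
      latitude >= grid$lat_min[i] & latitude <= grid$lat_max[i] &
      longitude >= grid$lon_min[i] & longitude <= grid$lon_max[i]
    out[hit] <- grid$macro_region[i]
  }
  out
}

#' Colony-level lineage frequencies at a location and year
#'
#' Evaluates the multinomial-logit cline surface of a [sim_config()]:
#' the softmax of the three lineage linear predictors, including any
#' island offset and macro-region drift multiplier applying at the
#' location. Deterministic given its inputs.
#'
#' @param config A `sim_config`.
#' @param latitude,longitude Coordinates (vectorised, equal length).
#' @param year Production year (scalar or vector).
#' @param macro_region Optional macro-region label(s); looked up from the
#'   region grid when omitted (locations outside every box get no island
#'   offset and full drift).
#' @return A tibble with columns `p_A`, `p_C`, `p_M`; rows sum to 1.
#' @export
#' @examples
#' cfg <- sim_config()
#' lineage_frequencies(cfg, 45, 9, 2018)
lineage_frequencies <- function(config, latitude, longitude, year,
                                macro_region = NULL) {
  n <- max(length(latitude), length(longitude), length(year))
  latitude <- rep_len(latitude, n); longitude <- rep_len(longitude, n)
  year <- rep_len(year, n)
  if (is.null(macro_region)) {
    macro_region <- locate_macro(config, latitude, longitude)
  } else {
    macro_region <- rep_len(macro_region, n)
  }
  year0 <- min(config$years)
  dmult <- ifelse(is.na(macro_region), 1,
                  unname(config$drift_mult[macro_region]))
  dmult[is.na(dmult)] <- 1
  eta <- matrix(0, n, 3, dimnames = list(NULL, c("A", "C", "M")))
  for (L in c("A", "C", "M")) {
    cf <- config$coefficients[config$coefficients$lineage == L, ]
    eta[, L] <- cf$alpha +
      cf$beta_lat * (latitude - config$centre[["lat0"]]) +
      cf$beta_lon * (longitude - config$centre[["lon0"]]) +
      cf$gamma * dmult * (year - year0)
  }
  for (macro in names(config$island_offsets)) {
    off <- config$island_offsets[[macro]]
    rows <- !is.na(macro_region) & macro_region == macro
    if (any(rows)) {
      for (L in names(off)) eta[rows, L] <- eta[rows, L] + off[[L]]
    }
  }
  expeta <- exp(eta - apply(eta, 1, max))
  p <- expeta / rowSums(expeta)
  tibble::tibble(p_A = unname(p[, "A"]), p_C = unname(p[, "C"]),
                 p_M = unname(p[, "M"]))
}

# Vectorised pattern draw: for each row, k colonies are drawn i.i.d. from
# (p_A, p_C, p_M); each colony contributes its lineage with probability d;
# the pattern is the union of contributing lineages. Empty unions
# (possible only when d < 1) are redrawn, since observed honey samples
# always amplify at least one lineage.
draw_patterns <- function(p, k, d) {
  n <- nrow(p)
  m_A <- stats::rbinom(n, k, p$p_A)
  p_C_rest <- ifelse(p$p_A < 1, p$p_C / (1 - p$p_A), 0)
  m_C <- stats::rbinom(n, k - m_A, pmin(1, p_C_rest))
  m_M <- k - m_A - m_C
  has_A <- stats::rbinom(n, m_A, d) > 0
  has_C <- stats::rbinom(n, m_C, d) > 0
  has_M <- stats::rbinom(n, m_M, d) > 0
  empty <- which(!(has_A | has_C | has_M))
  while (length(empty) > 0) {
    i <- empty
    has_A[i] <- stats::rbinom(length(i), m_A[i], d) > 0
    has_C[i] <- stats::rbinom(length(i), m_C[i], d) > 0
    has_M[i] <- stats::rbinom(length(i), m_M[i], d) > 0
    empty <- i[!(has_A[i] | has_C[i] | has_M[i])]
  }
  paste0(ifelse(has_A, "A", ""), ifelse(has_C, "C", ""), ifelse(has_M, "M", ""))
}

#' Simulate pooled honey sample patterns at a location
#'
#' Draws `n` honey sample patterns at one location and year: pool size
#' `k ~ DiscreteUniform(k_min, k_max)`, `k` colony lineages i.i.d. from
#' [lineage_frequencies()], each colony contributing its lineage with
#' probability `detect_d`; the pattern is the union of contributing
#' lineages (redrawn if empty, which can occur only when `detect_d < 1`).
#'
#' @param config A `sim_config`.
#' @param latitude,longitude Location.
#' @param year Production year.
#' @param n Number of samples to draw.
#' @return Character vector of `n` canonical patterns.
#' @export
simulate_honey_sample <- function(config, latitude, longitude, year, n = 1) {
  p <- lineage_frequencies(config, latitude, longitude, year)
  p <- p[rep(1, n), ]
  k <- resample(seq.int(config$pool_k[1], config$pool_k[2]), n)
  draw_patterns(p, k, config$detect_d)
}

#' Simulate a full synthetic honey sample table
#'
#' Places beekeepers at fixed uniform locations inside weighted region
#' boxes, draws each beekeeper's active years from the participation law,
#' the number of same-year samples from the redundancy law, and each
#' sample's lineage pattern from the pooled-union model. The output has
#' the same schema that [read_samples()] reads, and is fully reproducible
#' from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return Honey sample tibble (`sample_id`, `beekeeper_id`, `year`,
#'   `latitude`, `longitude`, `region`, `macro_region`, `pattern`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- tibble::tibble(
    sample_id = character(0), beekeeper_id = character(0),
    year = integer(0), latitude = numeric(0), longitude = numeric(0),
    region = character(0), macro_region = character(0), pattern = character(0)
  )
  if (config$n_beekeepers == 0) return(empty)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  grid <- config$region_grid
  nb <- config$n_beekeepers
  reg_idx <- sample.int(nrow(grid), nb, replace = TRUE,
                        prob = grid$weight / sum(grid$weight))
  bk <- tibble::tibble(
    beekeeper_id = sprintf("BK%05d", seq_len(nb)),
    region = grid$region[reg_idx],
    macro_region = grid$macro_region[reg_idx],
    latitude = stats::runif(nb, grid$lat_min[reg_idx], grid$lat_max[reg_idx]),
    longitude = stats::runif(nb, grid$lon_min[reg_idx], grid$lon_max[reg_idx]),
    u = if (config$beekeeper_sd > 0) stats::rnorm(nb, 0, config$beekeeper_sd) else 0
  )

  n_years <- resample(seq_along(config$years), nb,
                      prob = config$participation_law)
  bk_years <- purrr::map2_dfr(seq_len(nb), n_years, function(i, ny) {
    yrs <- config$years[sample.int(length(config$years), ny)]
    tibble::tibble(bk_row = i, year = sort(yrs))
  })
  n_samp <- resample(1:9, nrow(bk_years), prob = config$redundancy_law)
  rows <- bk_years[rep(seq_len(nrow(bk_years)), n_samp), ]
  out <- dplyr::bind_cols(bk[rows$bk_row, ], rows["year"])

  p <- lineage_frequencies(config, out$latitude, out$longitude, out$year,
                           macro_region = out$macro_region)
  if (config$beekeeper_sd > 0) {
    # random intercept shifts the A and M predictors jointly on the logit
    # scale; recompute softmax from implied etas
    eta_A <- log(pmax(p$p_A, 1e-300) / pmax(p$p_C, 1e-300)) + out$u
    eta_M <- log(pmax(p$p_M, 1e-300) / pmax(p$p_C, 1e-300)) + out$u
    denom <- 1 + exp(eta_A) + exp(eta_M)
    p <- tibble::tibble(p_A = exp(eta_A) / denom, p_C = 1 / denom,
                        p_M = exp(eta_M) / denom)
  }
  k <- resample(seq.int(config$pool_k[1], config$pool_k[2]), nrow(out))
  pattern <- draw_patterns(p, k, config$detect_d)

  out |>
    dplyr::mutate(sample_id = sprintf("HS%06d", dplyr::row_number()),
                  pattern = pattern) |>
    dplyr::select("sample_id", "beekeeper_id", "year", "latitude",
                  "longitude", "region", "macro_region", "pattern") |>
    dplyr::arrange(.data$sample_id)
}
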