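#' Per-beekeeper lineage diversity series
#'
#' For each beekeeper and production year, diversity is the number of
#' distinct mtDNA lineages (1 to 3) in the union of all that beekeeper's
#' sample patterns for the year (a beekeeper with samples {C} and {A,C}
#' in one year scores 2). Beekeepers observed in fewer than `min_years`
#' years are retained in the census but flagged ineligible for trend
#' testing.
#'
#' @param samples Honey sample tibble.
#' @param min_years Minimum number of observed years for trend
#'   eligibility (default 4).
#' @return Tibble with one row per beekeeper-year: `beekeeper_id`,
#'   `macro_region`, `year`, `diversity`, `n_years`, `trend_eligible`,
#'   sorted by beekeeper and year.
#' @export
build_diversity_series <- function(samples, min_years = 4) {
  samples |>
    dplyr::group_by(.data$beekeeper_id, .data$year) |>
    dplyr::summarise(
      macro_region = dplyr::first(.data$macro_region),
      diversity = length(unique(unlist(strsplit(.data$pattern, "", fixed = TRUE)))),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(n_years = dplyr::n(),
                  trend_eligible = .data$n_years >= min_years) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$beekeeper_id, .data$year)
}

#' Mann-Kendall score, Kendall's tau and tie-corrected variance
#'
#' For an ordered series, `S = sum_{i<j} sign(x_j - x_i)`; `tau` is the
#' tie-adjusted tau-b coefficient (time order has no ties, values may);
#' `var_S` uses the standard tie-corrected formula
#' `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of size t.
#' A constant series is degenerate: S = 0, tau defined as 0, var_S = 0.
#'
#' @param values Ordered numeric series, length >= 2.
#' @return A list with `S`, `tau`, `var_S`, `n`, `D` (the untied pair
#'   count n(n-1)/2) and `degenerate`.
#' @export
#' @examples
#' kendall_S_tau(c(1, 2, 3, 4))
kendall_S_tau <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2 || any(is.na(x))) {
    stop("need a complete series of length >= 2", call. = FALSE)
  }
  d <- outer(x, x, "-")
  S <- sum(sign(d[lower.tri(d)]))
  D <- n * (n - 1) / 2
  ties <- as.integer(table(x))
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  U <- sum(ties * (ties - 1) / 2)
  degenerate <- (D - U) <= 0
  tau <- if (degenerate) 0 else S / sqrt(D * (D - U))
  list(S = S, tau = tau, var_S = var_S, n = n, D = D, degenerate = degenerate)
}

#' Hamed-Rao autocorrelation correction of the Mann-Kendall variance
#'
#' Computes lag autocorrelations of the rank-transformed series, retains
#' the lags significant at `alpha` (two-sided normal approximation,
#' `|rho(i)| > z_{1-alpha/2} / sqrt(n)`, lags up to `n - 3`), and inflates
#' the variance by
#' `1 + 2 / (n(n-1)(n-2)) * sum_i (n-i)(n-i-1)(n-i-2) * rho(i)`
#' over the retained lags. The factor is floored (default 0.01) so the
#' corrected variance stays positive when strong negative autocorrelation
#' is estimated from a short series. A series with no significant lag
#' autocorrelation gets correction exactly 1.
#'
#' @param values Ordered numeric series, length >= 4.
#' @param alpha Two-sided significance level for retaining lags.
#' @param floor Lower bound on the correction factor.
#' @return A list with `correction` and `var_S_star`
#'   (`var_S * correction`).
#' @export
mmk_corrected_variance <- function(values, alpha = 0.05, floor = 1e-2) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4) stop("need a series of length >= 4", call. = FALSE)
  ks <- kendall_S_tau(x)
  r <- rank(x)
  rc <- r - mean(r)
  denom <- sum(rc^2)
  max_lag <- n - 3
  correction <- 1
  if (denom > 0 && max_lag >= 1) {
    crit <- stats::qnorm(1 - alpha / 2) / sqrt(n)
    acc <- 0
    for (i in seq_len(max_lag)) {
      rho_i <- sum(rc[seq_len(n - i)] * rc[seq_len(n - i) + i]) / denom
      if (abs(rho_i) > crit) {
        acc <- acc + (n - i) * (n - i - 1) * (n - i - 2) * rho_i
      }
    }
    correction <- 1 + 2 / (n * (n - 1) * (n - 2)) * acc
    correction <- max(correction, floor)
  }
  list(correction = correction, var_S_star = ks$var_S * correction)
}

#' Modified Mann-Kendall trend test for one diversity series
#'
#' Combines [kendall_S_tau()] and [mmk_corrected_variance()]:
#' `z = (S - sign(S)) / sqrt(var_S_star)` with the standard continuity
#' correction, two-sided normal p-value, and a variance for tau suitable
#' for meta-analysis, `var_tau = var_S_star / D^2` with the untied
#' denominator `D = n(n-1)/2` (tau-b denominators are unstable for heavily
#' tied short series, so the untied pair count is used; configurable via
#' `tau_denominator`).
#'
#' Constant series are degenerate: tau = 0 is reported with the variance
#' from the untied formula `n(n-1)(2n+5)/18` so downstream meta-analysis
#' can still consume the estimate, and the `degenerate` flag is set.
#'
#' @param values Ordered numeric series (length >= 4), e.g. one
#'   beekeeper's yearly lineage diversity. Calendar-year order is used;
#'   Kendall statistics depend only on order, not spacing, so gap years
#'   need no special handling.
#' @param alpha,floor Passed to [mmk_corrected_variance()].
#' @param tau_denominator `"untied"` (default) or `"tau_b"` for
#'   `var_tau`.
#' @return One-row tibble: `n`, `S`, `tau`, `var_S`, `correction`,
#'   `var_S_star`, `var_tau`, `z`, `p`, `degenerate`.
#' @export
#' @examples
#' mk_test(c(1, 1, 2, 3, 3))
mk_test <- function(values, alpha = 0.05, floor = 1e-2,
                    tau_denominator = c("untied", "tau_b")) {
  tau_denominator <- match.arg(tau_denominator)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4) stop("need a series of length >= 4", call. = FALSE)
  ks <- kendall_S_tau(x)
  if (ks$degenerate || ks$var_S == 0) {
    var_untied <- n * (n - 1) * (2 * n + 5) / 18
    return(tibble::tibble(
      n = n, S = ks$S, tau = 0, var_S = ks$var_S, correction = 1,
      var_S_star = ks$var_S, var_tau = var_untied / ks$D^2,
      z = 0, p = 1, degenerate = TRUE
    ))
  }
  mm <- mmk_corrected_variance(x, alpha = alpha, floor = floor)
  denom2 <- if (tau_denominator == "untied") {
    ks$D^2
  } else {
    ties <- as.integer(table(x)); ties <- ties[ties > 1]
    U <- sum(ties * (ties - 1) / 2)
    ks$D * (ks$D - U)
  }
  z <- if (ks$S == 0) 0 else (ks$S - sign(ks$S)) / sqrt(mm$var_S_star)
  tibble::tibble(
    n = n, S = ks$S, tau = ks$tau, var_S = ks$var_S,
    correction = mm$correction, var_S_star = mm$var_S_star,
    var_tau = mm$var_S_star / denom2,
    z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE
  )
}

#' Modified Mann-Kendall trends for all eligible beekeepers
#'
#' Builds the per-beekeeper diversity series and applies [mk_test()] to
#' every beekeeper observed in at least `min_years` years.
#'
#' @param samples Honey sample tibble.
#' @param min_years Minimum observed years for inclusion (default 4).
#' @inheritParams mk_test
#' @return Tibble with one row per eligible beekeeper: `beekeeper_id`,
#'   `macro_region`, plus the [mk_test()] columns.
#' @export
mk_trend <- function(samples, min_years = 4, alpha = 0.05, floor = 1e-2,
                     tau_denominator = c("untied", "tau_b")) {
  tau_denominator <- match.arg(tau_denominator)
  series <- build_diversity_series(samples, min_years = min_years) |>
    dplyr::filter(.data$trend_eligible)
  series |>
    dplyr::group_by(.data$beekeeper_id) |>
    dplyr::summarise(
      macro_region = dplyr::first(.data$macro_region),
      res = list(mk_test(.data$diversity[order(.data$year)],
                         alpha = alpha, floor = floor,
                         tau_denominator = tau_denominator)),
      .groups = "drop"
    ) |>
    tidyr::unnest("res")
}
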