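#' Detection probability of a lineage in a pooled honey sample
#'
#' Honey carries DNA from all colonies that contributed to it, so the
#' pooled pattern contains a lineage whenever at least one contributing
#' colony carries it. With colony-level lineage frequency `p`, pool size
#' `k` colonies and per-colony detection probability `d`, the detection
#' probability is `1 - (1 - p * d)^k`.
#'
#' @param p Colony-level lineage frequency, in \[0, 1\]. Vectorised.
#' @param k Pool size: positive integer number of colonies. Vectorised.
#' @param d Per-colony detection probability, in (0, 1\].
#' @return Probability that the pooled sample's pattern contains the lineage.
#' @export
#' @examples
#' detect_prob(0.05, 20)
detect_prob <- function(p, k, d = 1) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k < 1) || any(k != floor(k))) {
    stop("k must be a positive integer pool size", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d <= 0 | d > 1)) {
    stop("d must be in (0, 1]", call. = FALSE)
  }
  1 - (1 - p * d)^k
}

#' Detection probability under a pool-size distribution
#'
#' Averages [detect_prob()] over a distribution of pool sizes:
#' `sum_k P(k) * (1 - (1 - p * d)^k)`. The default pool-size law used in
#' the synthetic generator is discrete uniform on 10..30 colonies.
#'
#' @param p Colony-level lineage frequency (scalar or vector).
#' @param pool_law Either a named numeric vector of probabilities (names
#'   are pool sizes) or a data frame with columns `k` and `prob`.
#' @param d Per-colony detection probability.
#' @return Expected detection probability, vectorised over `p`.
#' @export
#' @examples
#' expected_detect_prob(0.013, uniform_pool_law(10, 30))
expected_detect_prob <- function(p, pool_law, d = 1) {
  law <- normalise_pool_law(pool_law)
  vapply(p, function(pi) sum(law$prob * detect_prob(pi, law$k, d)), numeric(1))
}

#' Discrete uniform pool-size law
#'
#' @param k_min,k_max Integer bounds (inclusive); defaults 10 and 30
#'   colonies, the plausible range of colonies contributing DNA to one
#'   honey sample.
#' @return Tibble with columns `k` and `prob`.
#' @export
uniform_pool_law <- function(k_min = 10, k_max = 30) {
  stopifnot(k_min >= 1, k_max >= k_min)
  k <- seq.int(k_min, k_max)
  tibble::tibble(k = k, prob = rep(1 / length(k), length(k)))
}

normalise_pool_law <- function(pool_law) {
  if (is.data.frame(pool_law)) {
    if (!all(c("k", "prob") %in% names(pool_law))) {
      stop("pool_law data frame needs columns 'k' and 'prob'", call. = FALSE)
    }
    law <- tibble::tibble(k = as.numeric(pool_law$k), prob = as.numeric(pool_law$prob))
  } else if (is.numeric(pool_law) && !is.null(names(pool_law))) {
    law <- tibble::tibble(k = as.numeric(names(pool_law)), prob = as.numeric(pool_law))
  } else {
    stop("pool_law must be a data frame (k, prob) or a named numeric vector",
         call. = FALSE)
  }
  if (any(!is.finite(law$prob)) || any(law$prob < 0) ||
      abs(sum(law$prob) - 1) > 1e-8 ||
      any(law$k < 1) || any(law$k != floor(law$k))) {
    stop("pool_law must be a probability distribution over positive integers",
         call. = FALSE)
  }
  law
}

#' Honey-versus-individual-bee sensitivity (inflation) factor
#'
#' Ratio of the frequency at which pooled honey samples detect a lineage
#' to its frequency among individually analysed bees. A pool detects a
#' lineage if any contributing colony carries it, so the ratio exceeds 1
#' for low-frequency lineages.
#'
#' @param honey_freq Detection frequency among honey samples (proportion).
#' @param bee_freq Carrier frequency among individual bees (proportion, > 0).
#' @param digits Decimal places for the reported ratio (half-up), default 2.
#' @return The rounded ratio `honey_freq / bee_freq`.
#' @export
#' @examples
#' inflation_factor(34 / 576, 0.024)
inflation_factor <- function(honey_freq, bee_freq, digits = 2) {
  if (any(!is.finite(bee_freq)) || any(bee_freq <= 0)) {
    stop("bee_freq must be > 0", call. = FALSE)
  }
  if (any(!is.finite(honey_freq)) || any(honey_freq < 0)) {
    stop("honey_freq must be a non-negative proportion", call. = FALSE)
  }
  round_half_up(honey_freq / bee_freq, digits)
}

#' Detection probability and inflation curves
#'
#' Tabulates, over a grid of colony-level frequencies, the pooled
#' detection probability under a pool-size law and the implied inflation
#' factor relative to individual-bee analysis (bee-level frequency equals
#' colony-level frequency under mono-mitotype colonies).
#'
#' @param p Vector of colony-level frequencies.
#' @param pool_law Pool-size law, default uniform on 10..30.
#' @param d Per-colony detection probability.
#' @return Tibble with `p`, `detect_prob`, `inflation`.
#' @export
detection_curve <- function(p = seq(0.001, 0.2, by = 0.001),
                            pool_law = uniform_pool_law(), d = 1) {
  dp <- expected_detect_prob(p, pool_law, d)
  tibble::tibble(p = p, detect_prob = dp, inflation = dp / p)
}
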