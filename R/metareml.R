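#' Restricted log-likelihood of a random-effects meta-analytic model
#'
#' For estimates `y` with sampling variances `v`, fixed-effect design
#' matrix `X` and between-study variance `tau2`, the restricted
#' log-likelihood is
#' `-1/2 [ sum log(v_i + tau2) + log|X' W X| + r' W r ]` (up to an
#' additive constant), with `W = diag(1/(v_i + tau2))` and `r` the
#' residual from the weighted least-squares fit at this `tau2`.
#'
#' @param tau2 Between-study variance (>= 0).
#' @param y Numeric vector of estimates.
#' @param v Positive sampling variances.
#' @param X Design matrix (default intercept-only).
#' @return The restricted log-likelihood value.
#' @export
reml_loglik <- function(tau2, y, v, X = matrix(1, length(y), 1)) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  beta <- solve(XtWX, crossprod(X * w, y))
  r <- y - drop(X %*% beta)
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

# REML score: d l_R / d tau2 = -1/2 [ tr(P) - y' P P y ], with
# P = W - W X (X'WX)^-1 X'W and P y = W r.
reml_score <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  XtWX_inv <- solve(XtWX)
  beta <- XtWX_inv %*% crossprod(X * w, y)
  r <- y - drop(X %*% beta)
  XtW2X <- crossprod(X * w^2, X)
  tr_P <- sum(w) - sum(XtWX_inv * XtW2X)
  -0.5 * (tr_P - sum((w * r)^2))
}

#' REML estimate of the between-study variance
#'
#' Maximises the restricted log-likelihood over `tau2 >= 0` by a
#' safeguarded one-dimensional root search on the REML score: if the
#' score at zero is non-positive the boundary estimate 0 is returned,
#' otherwise the score's sign change is bracketed by doubling and solved
#' with Brent's method (bisection-safeguarded) to `1e-12` tolerance.
#'
#' @param y Estimates (e.g. per-beekeeper Kendall tau values).
#' @param v Sampling variances (> 0).
#' @param X Design matrix; default intercept-only. Must have fewer
#'   columns than there are estimates.
#' @return The REML estimate of `tau2`.
#' @export
#' @examples
#' set.seed(1)
#' y <- rnorm(50, 0.1, sqrt(0.04 + 0.01))
#' reml_tau2(y, rep(0.01, 50))
reml_tau2 <- function(y, v, X = matrix(1, length(y), 1)) {
  y <- as.numeric(y); v <- as.numeric(v)
  X <- as.matrix(X)
  k <- length(y)
  if (length(v) != k || nrow(X) != k) stop("dimension mismatch", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(!is.finite(X))) {
    stop("non-finite inputs", call. = FALSE)
  }
  if (any(v <= 0)) stop("sampling variances must be > 0", call. = FALSE)
  if (k <= ncol(X)) {
    stop("need more estimates than fixed-effect coefficients", call. = FALSE)
  }
  if (reml_score(0, y, v, X) <= 0) return(0)
  upper <- max(stats::var(y), mean(v), 1e-6)
  for (i in 1:60) {
    if (reml_score(upper, y, v, X) < 0) break
    upper <- upper * 2
  }
  if (reml_score(upper, y, v, X) >= 0) return(upper)
  root <- stats::uniroot(reml_score, c(0, upper), y = y, v = v, X = X,
                         tol = 1e-12)
  root$root
}

#' Random-effects meta-analysis of per-beekeeper Kendall tau
#'
#' Pools per-beekeeper trend estimates (Kendall's tau with their
#' variances, as produced by [mk_trend()]) in a random-effects model with
#' a geographic moderator: either the five areas (North, Central, South,
#' Sicily, Sardinia) or the macro-area scheme collapsing Central and
#' South (North, Central-South, Sicily, Sardinia). The moderator is coded
#' as dummy variables without intercept, so each coefficient is its
#' level's pooled mean tau. Between-study variance is estimated by REML
#' ([reml_tau2()]); weights are `1/(v_i + tau2)`; confidence intervals
#' are normal-based at `level` (or Knapp-Hartung adjusted when
#' `knapp_hartung = TRUE`).
#'
#' @param data Tibble with one estimate per row, e.g. [mk_trend()]
#'   output; needs columns `macro_region` and the estimate/variance
#'   columns named by `estimate` and `variance`.
#' @param scheme `"areas"` (five levels) or `"macro_areas"`
#'   (Central-South combined).
#' @param estimate,variance Column names (strings) of the estimates and
#'   their sampling variances.
#' @param exclude_degenerate Drop estimates flagged degenerate (constant
#'   diversity series)? Default FALSE: they carry real "no change"
#'   information and no exclusion rule is imposed.
#' @param knapp_hartung Use the Knapp-Hartung small-sample adjustment
#'   (t-based CIs with residual-scaled SEs)? Default FALSE.
#' @param level Confidence level, default 0.95.
#' @return An object of class `meta_fit`; see [tidy.meta_fit()],
#'   [glance.meta_fit()] and [autoplot.meta_fit()].
#' @export
fit_meta <- function(data, scheme = c("areas", "macro_areas"),
                     estimate = "tau", variance = "var_tau",
                     exclude_degenerate = FALSE,
                     knapp_hartung = FALSE, level = 0.95) {
  scheme <- match.arg(scheme)
  if (exclude_degenerate && "degenerate" %in% names(data)) {
    data <- dplyr::filter(data, !.data$degenerate)
  }
  lev_map <- if (scheme == "macro_areas") {
    c(North = "North", Central = "Central-South", South = "Central-South",
      Sicily = "Sicily", Sardinia = "Sardinia")
  } else {
    c(North = "North", Central = "Central", South = "South",
      Sicily = "Sicily", Sardinia = "Sardinia")
  }
  area <- unname(lev_map[data$macro_region])
  if (anyNA(area)) stop("unknown macro_region level(s)", call. = FALSE)
  lev_order <- intersect(unique(unname(lev_map)), area)
  f <- factor(area, levels = lev_order)
  y <- data[[estimate]]
  v <- data[[variance]]
  if (any(v <= 0)) stop("sampling variances must be > 0", call. = FALSE)
  # dummy coding without intercept (built directly so a single level works)
  X <- vapply(lev_order, function(l) as.numeric(area == l),
              numeric(length(area)))

  tau2 <- reml_tau2(y, v, X)
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  XtWX_inv <- solve(XtWX)
  beta <- unname(drop(XtWX_inv %*% crossprod(X * w, y)))
  se <- unname(sqrt(diag(XtWX_inv)))
  k <- length(y)
  p <- ncol(X)
  r <- y - drop(X %*% beta)
  if (knapp_hartung) {
    s2 <- sum(w * r^2) / (k - p)
    se <- se * sqrt(s2)
    crit <- stats::qt(1 - (1 - level) / 2, df = k - p)
  } else {
    crit <- stats::qnorm(1 - (1 - level) / 2)
  }

  # residual heterogeneity with fixed-effect (1/v) weights
  w_fe <- 1 / v
  XtWX_fe <- crossprod(X * w_fe, X)
  beta_fe <- drop(solve(XtWX_fe, crossprod(X * w_fe, y)))
  QE <- sum(w_fe * (y - drop(X %*% beta_fe))^2)
  QE_df <- k - p
  counts <- as.integer(table(f))
  zval <- beta / se

  rows <- tibble::tibble(
    level = lev_order, k = counts, estimate = beta, se = se,
    ci_lo = beta - crit * se, ci_hi = beta + crit * se,
    z = zval, p = 2 * stats::pnorm(-abs(zval)),
    single_estimate = counts == 1L
  )
  structure(list(
    scheme = scheme, tau2 = tau2, coefficients = rows, k = k,
    QE = QE, QE_df = QE_df,
    QE_p = stats::pchisq(QE, df = QE_df, lower.tail = FALSE),
    level = level, knapp_hartung = knapp_hartung,
    data = tibble::tibble(area = area, y = y, v = v)
  ), class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s scheme, k = %d)\n",
              x$scheme, x$k))
  cat(sprintf("  tau2 (between-study, REML) = %.5f\n", x$tau2))
  cat(sprintf("  QE = %.2f on %d df (p %.3g)\n", x$QE, x$QE_df, x$QE_p))
  print(x$coefficients)
  invisible(x)
}

#' Forest-plot rows of a meta-analysis fit
#'
#' @param x A `meta_fit`.
#' @param ... Unused.
#' @return One row per moderator level: pooled tau, CI bounds,
#'   contributing-beekeeper count.
#' @export
tidy.meta_fit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a meta-analysis fit
#'
#' @param x A `meta_fit`.
#' @param ... Unused.
#' @return One-row tibble with `tau2`, `k`, `QE`, `QE_df`, `QE_p`.
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(tau2 = x$tau2, k = x$k, QE = x$QE, QE_df = x$QE_df,
                 QE_p = x$QE_p, scheme = x$scheme, level = x$level)
}

#' Forest plot of pooled Kendall tau by geographic area
#'
#' Dot size is proportional to the number of contributing beekeepers;
#' horizontal segments are the confidence intervals.
#'
#' @param object A `meta_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_fit <- function(object, ...) {
  rows <- object$coefficients
  rows$level <- factor(rows$level, levels = rev(rows$level))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$estimate, y = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k), colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "Pooled Kendall's tau", y = NULL, size = "Beekeepers") +
    ggplot2::theme_minimal()
}
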