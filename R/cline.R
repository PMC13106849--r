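#' Code honey sample patterns as a binary outcome
#'
#' Adds a 0/1 outcome column `y` according to a coding (see
#' [coding_levels()]). In `include` mode every sample is eligible and
#' `y = 1` iff the pattern contains the lineage. In `exclude` mode,
#' samples with multi-lineage patterns are dropped before coding, so
#' `y = 1` iff the pattern is exactly that single lineage. The `only-L`
#' codings retain all samples and set `y = 1` iff the pattern is exactly
#' {L}; the `multi_lineage` argument does not apply to them.
#'
#' @param samples Honey sample tibble.
#' @param coding One of the six binary codings.
#' @param multi_lineage `"include"` (default) or `"exclude"`.
#' @return The samples (possibly with multi-lineage rows dropped) plus a
#'   column `y`.
#' @export
code_outcome <- function(samples, coding, multi_lineage = c("include", "exclude")) {
  coding <- match.arg(coding, coding_levels())
  multi_lineage <- match.arg(multi_lineage)
  if (startsWith(coding, "contains") && multi_lineage == "exclude") {
    samples <- dplyr::filter(samples, nchar(.data$pattern) == 1L)
    lineage <- sub("^contains-", "", coding)
    return(dplyr::mutate(samples, y = as.integer(.data$pattern == lineage)))
  }
  dplyr::mutate(samples, y = apply_coding(.data$pattern, coding))
}

#' Univariate logistic regression by IRLS
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 * x` by
#' iteratively reweighted least squares, with convergence declared when
#' the relative deviance change falls below `1e-8` (25 iterations
#' maximum). Reports the Wald test on the slope and the 1-df
#' likelihood-ratio model chi-square against the intercept-only model.
#' Complete or quasi-separation (deviance driven toward an infinite
#' slope) is detected and flagged rather than reported as a converged
#' estimate.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Numeric predictor vector (not constant), same length.
#' @return An object of class `cline_fit`; see [tidy.cline_fit()] and
#'   [glance.cline_fit()].
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(200, 38, 46)
#' y <- rbinom(200, 1, plogis(10 - 0.25 * x))
#' glance(fit_logistic(y, x))
fit_logistic <- function(y, x) {
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(is.na(y)) || any(is.na(x))) stop("missing values in y or x", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  s <- sum(y)
  if (s == 0 || s == n) {
    stop("degenerate fit: outcome is all ", if (s == 0) "0" else "1", call. = FALSE)
  }

  X <- cbind(1, x)
  # glm-style initialisation: one WLS step from mu = (y + 1/2) / 2
  mu <- (y + 0.5) / 2
  eta <- stats::qlogis(mu)
  beta <- c(0, 0)
  dev_old <- Inf
  dev <- NA_real_
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  deviances <- numeric(0)
  for (iter in seq_len(25L)) {
    w <- mu * (1 - mu)
    if (any(w < 1e-14)) { separated <- TRUE; break }
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(unname(drop(solve(XtW %*% X, XtW %*% z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) { separated <- TRUE; break }
    # step-halving keeps the deviance non-increasing
    beta_old <- beta
    step <- beta_new - beta_old
    halvings <- 0L
    repeat {
      beta <- beta_old + step
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      dev <- binom_deviance(y, mu)
      if (iter == 1L || !is.finite(dev_old) || dev <= dev_old ||
          halvings >= 20L) break
      step <- step / 2
      halvings <- halvings + 1L
    }
    deviances <- c(deviances, dev)
    if (max(abs(eta)) > 30) { separated <- TRUE; break }
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-8) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (converged) {
    # polish to the stationary point: the deviance criterion can leave the
    # last Newton refinement unapplied
    for (extra in 1:3) {
      w <- mu * (1 - mu)
      grad <- unname(drop(crossprod(X, y - mu)))
      if (sqrt(sum(grad^2)) < 1e-10) break
      upd <- tryCatch(unname(drop(solve(t(X * w) %*% X, grad))),
                      error = function(e) NULL)
      if (is.null(upd)) break
      beta <- beta + upd
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      dev <- binom_deviance(y, mu)
      deviances <- c(deviances, dev)
    }
  }

  mu_bar <- s / n
  dev_null <- binom_deviance(y, rep(mu_bar, n))
  if (separated || !converged) {
    return(new_cline_fit(
      n = n, beta = beta, se = NA_real_, z = NA_real_, p_wald = NA_real_,
      lr_chisq = max(0, dev_null - dev), p_lr = NA_real_,
      deviance = dev, null_deviance = dev_null,
      converged = FALSE, separated = separated, iterations = iter,
      dev_trace = deviances, y = y, x = x
    ))
  }
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  vcov <- solve(info)
  se <- sqrt(vcov[2, 2])
  zstat <- beta[2] / se
  lr <- max(0, dev_null - dev)
  new_cline_fit(
    n = n, beta = beta, se = se, z = zstat,
    p_wald = 2 * stats::pnorm(-abs(zstat)),
    lr_chisq = lr, p_lr = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    deviance = dev, null_deviance = dev_null,
    converged = TRUE, separated = FALSE, iterations = iter,
    dev_trace = deviances, y = y, x = x
  )
}

binom_deviance <- function(y, mu) {
  eps <- 1e-300
  -2 * sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
}

new_cline_fit <- function(n, beta, se, z, p_wald, lr_chisq, p_lr,
                          deviance, null_deviance, converged, separated,
                          iterations, dev_trace, y, x) {
  structure(list(
    n = n, intercept = beta[1], slope = beta[2], se = se, z = z,
    p_wald = p_wald, lr_chisq = lr_chisq, p_lr = p_lr,
    deviance = deviance, null_deviance = null_deviance,
    converged = converged, separated = separated, iterations = iterations,
    dev_trace = dev_trace, y = y, x = x
  ), class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("Logistic cline fit (n =", x$n, ")\n")
  cat(sprintf("  logit P(y=1) = %.4f %+.4f * x\n", x$intercept, x$slope))
  if (x$converged) {
    cat(sprintf("  slope SE %.4f, Wald z %.3f (p %.3g)\n", x$se, x$z, x$p_wald))
    cat(sprintf("  model chi-square %.3f on 1 df (p %.3g)\n", x$lr_chisq, x$p_lr))
  } else {
    cat("  NOT CONVERGED", if (x$separated) "(separation detected)", "\n")
  }
  invisible(x)
}

#' Tidy a logistic cline fit
#'
#' @param x A `cline_fit`.
#' @param ... Unused.
#' @return One row per coefficient with estimate, SE, statistic, p.value.
#' @export
tidy.cline_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se),
    statistic = c(NA_real_, x$z),
    p.value = c(NA_real_, x$p_wald)
  )
}

#' One-row summary of a logistic cline fit
#'
#' @param x A `cline_fit`.
#' @param ... Unused.
#' @return One-row tibble with n, slope, SE, Wald and LR statistics.
#' @export
glance.cline_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, intercept = x$intercept, slope = x$slope, se = x$se,
    z = x$z, p_wald = x$p_wald, lr_chisq = x$lr_chisq, p_lr = x$p_lr,
    deviance = x$deviance, null_deviance = x$null_deviance,
    converged = x$converged, separated = x$separated,
    iterations = x$iterations
  )
}

#' Plot a fitted logistic cline
#'
#' Observed binary outcomes (jittered) with the fitted logistic curve.
#'
#' @param object A `cline_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cline_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$x, y = object$y)
  grid <- tibble::tibble(x = seq(min(dat$x), max(dat$x), length.out = 200))
  grid$p <- stats::plogis(object$intercept + object$slope * grid$x)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_jitter(height = 0.03, width = 0, alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(y = "P(coding = 1)") +
    ggplot2::theme_minimal()
}

# Subset labels over macro-regions used throughout the cline analyses.
cline_subsets <- function() {
  list(
    "Peninsula" = c("North", "Central", "South"),
    "Peninsula+Sicily" = c("North", "Central", "South", "Sicily"),
    "Peninsula+Sicily+Sardinia" = c("North", "Central", "South", "Sicily", "Sardinia"),
    "North" = "North",
    "Central-South" = c("Central", "South")
  )
}

#' Run the full battery of cline regressions
#'
#' One logistic fit per combination of binary coding, predictor, sample
#' subset and period. Latitude fits run over the peninsular subsets
#' (optionally adding Sicily and Sardinia); longitude fits are restricted
#' to the Northern macro-region, the study's continuous west-east
#' transect; year-predictor fits run within macro-area groups (North and
#' Central+South) and include only years with more than `min_cell`
#' samples in that group, guarding against sparse-cell artefacts.
#' Fits are produced pooled over all years and separately per year.
#'
#' @param samples Honey sample tibble.
#' @param codings Binary codings to fit; default the three headline ones.
#' @param predictors Subset of `c("latitude", "longitude", "year")`.
#' @param multi_lineage Passed to [code_outcome()].
#' @param per_year Also fit each production year separately (latitude and
#'   longitude predictors only)?
#' @param min_cell Minimum samples per macro-area-by-year cell for the
#'   year-predictor fits (default 100).
#' @return A tibble with one row per attempted fit: coding, predictor,
#'   subset, period, n, estimates, tests and a `status` column (`"ok"`,
#'   `"degenerate"`, `"skipped"`).
#' @export
run_cline_battery <- function(samples,
                              codings = c("contains-A", "contains-M", "only-C"),
                              predictors = c("latitude", "longitude", "year"),
                              multi_lineage = "include",
                              per_year = TRUE,
                              min_cell = 100) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  subsets <- cline_subsets()
  subset_for <- list(
    latitude = c("Peninsula", "Peninsula+Sicily", "Peninsula+Sicily+Sardinia"),
    longitude = "North",
    year = c("North", "Central-South")
  )
  years <- sort(unique(samples$year))

  combos <- purrr::map_dfr(predictors, function(pred) {
    periods <- if (pred == "year" || !per_year) "pooled" else c("pooled", as.character(years))
    tidyr::expand_grid(coding = codings, predictor = pred,
                       subset = subset_for[[pred]], period = periods)
  })

  purrr::pmap_dfr(combos, function(coding, predictor, subset, period) {
    dat <- dplyr::filter(samples, .data$macro_region %in% subsets[[subset]])
    if (period != "pooled") dat <- dplyr::filter(dat, .data$year == as.integer(period))
    if (predictor == "year") {
      cell_ok <- dat |>
        dplyr::count(.data$year) |>
        dplyr::filter(.data$n > min_cell)
      dat <- dplyr::filter(dat, .data$year %in% cell_ok$year)
      if (length(unique(dat$year)) < 2) {
        return(battery_row(coding, predictor, subset, period, nrow(dat),
                           status = "skipped"))
      }
    }
    dat <- code_outcome(dat, coding, multi_lineage = multi_lineage)
    x <- dat[[predictor]]
    if (nrow(dat) < 3 || length(unique(x)) < 2 ||
        sum(dat$y) %in% c(0, nrow(dat))) {
      return(battery_row(coding, predictor, subset, period, nrow(dat),
                         status = if (nrow(dat) == 0) "skipped" else "degenerate"))
    }
    fit <- fit_logistic(dat$y, x)
    g <- glance(fit)
    battery_row(coding, predictor, subset, period, fit$n,
                status = if (fit$converged) "ok" else "degenerate",
                b0 = g$intercept, b1 = g$slope, se = g$se, z = g$z,
                p_wald = g$p_wald, lr_chisq = g$lr_chisq, p_lr = g$p_lr,
                converged = g$converged, iterations = g$iterations)
  })
}

battery_row <- function(coding, predictor, subset, period, n, status,
                        b0 = NA_real_, b1 = NA_real_, se = NA_real_,
                        z = NA_real_, p_wald = NA_real_, lr_chisq = NA_real_,
                        p_lr = NA_real_, converged = FALSE, iterations = NA_integer_) {
  tibble::tibble(coding = coding, predictor = predictor, subset = subset,
                 period = period, n = n, b0 = b0, b1 = b1, se = se, z = z,
                 p_wald = p_wald, lr_chisq = lr_chisq, p_lr = p_lr,
                 converged = converged, iterations = iterations,
                 status = status)
}
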