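test_that("outcome coding follows the include/exclude rules", {
  s <- make_samples("b", 2020, c("ACM", "C", "AC", "M", "CM"))
  inc <- code_outcome(s, "contains-A", "include")
  expect_equal(inc$y, c(1L, 0L, 1L, 0L, 0L))
  exc <- code_outcome(s, "contains-A", "exclude")
  expect_equal(nrow(exc), 2L)                    # multi-lineage rows dropped
  expect_equal(exc$y[exc$pattern == "C"], 0L)
  expect_equal(exc$y[exc$pattern == "M"], 0L)
  onlyc <- code_outcome(s, "only-C", "include")
  expect_equal(nrow(onlyc), 5L)                  # all samples retained
  expect_equal(onlyc$y, as.integer(s$pattern == "C"))
  expect_error(code_outcome(s, "contains-B"), "arg")
})

test_that("coded counts equal brute-force pattern recounts", {
  s <- random_samples(40, seed = 13)
  for (cd in coding_levels()) {
    got <- sum(code_outcome(s, cd)$y)
    L <- sub(".*-", "", cd)
    want <- if (startsWith(cd, "only")) {
      sum(s$pattern == L)
    } else {
      sum(vapply(strsplit(s$pattern, ""), function(ch) L %in% ch, logical(1)))
    }
    expect_equal(got, want)
  }
})

test_that("binary-predictor slope equals the closed-form log odds ratio", {
  # 2x2 cell counts (a, b; c, d), all positive
  cells <- list(c(13, 37, 22, 28), c(5, 95, 40, 60), c(50, 50, 50, 50))
  for (cc in cells) {
    a <- cc[1]; b <- cc[2]; c_ <- cc[3]; d <- cc[4]
    x <- c(rep(0, a + b), rep(1, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    fit <- fit_logistic(y, x)
    expect_equal(fit$slope, log((c_ / d) / (a / b)), tolerance = 1e-6)
  }
})

test_that("IRLS agrees with an independent reference implementation", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(50:400, 1)
      x <- runif(n, 36, 47)
      b0 <- runif(1, -3, 3); b1 <- runif(1, -0.5, 0.5)
      y <- rbinom(n, 1, plogis(b0 + b1 * x))
      if (sum(y) %in% c(0, n)) next
      fit <- fit_logistic(y, x)
      if (!fit$converged) next
      ref <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
      # glm reports the information from its penultimate weights, so the
      # standard errors agree a little less tightly than the estimates
      expect_equal(fit$se, sqrt(vcov(ref)[2, 2]), tolerance = 1e-4)
      expect_equal(fit$lr_chisq, ref$null.deviance - ref$deviance,
                   tolerance = 1e-6)
    }
  })
})

test_that("a known cline slope is recovered within sampling error", {
  withr::with_seed(23, {
    x <- runif(2000, 37, 47)
    y <- rbinom(2000, 1, plogis(11 + (-0.3) * x))
    fit <- fit_logistic(y, x)
    expect_true(fit$converged)
    expect_lt(abs(fit$slope - (-0.3)), 3 * fit$se)
  })
})

test_that("IRLS deviance decreases monotonically and ends at a stationary point", {
  withr::with_seed(29, {
    x <- runif(3000, 36, 47)
    y <- rbinom(3000, 1, plogis(6 - 0.15 * x))
  })
  fit <- fit_logistic(y, x)
  expect_true(all(diff(fit$dev_trace) <= 1e-8))
  grad <- crossprod(cbind(1, x),
                    y - plogis(fit$intercept + fit$slope * x))
  expect_lt(sqrt(sum(grad^2)), 1e-6)
  expect_gte(fit$lr_chisq, 0)
})

test_that("degenerate and separated fits are flagged, not reported", {
  expect_error(fit_logistic(rep(1, 10), 1:10), "degenerate")
  expect_error(fit_logistic(rep(0, 10), 1:10), "degenerate")
  expect_error(fit_logistic(c(0, 1, 0, 1), rep(2, 4)), "constant")
  # complete separation
  x <- c(1:10, 11:20)
  y <- c(rep(0, 10), rep(1, 10))
  fit <- fit_logistic(y, x)
  expect_false(fit$converged)
  expect_true(fit$separated)
  expect_true(is.na(fit$se))
})

test_that("the battery covers its combination grid and flags degenerate cells", {
  cfg <- tiny_config(seed = 31, n_beekeepers = 400)
  d <- simulate_dataset(cfg)
  bat <- run_cline_battery(d)
  years <- sort(unique(d$year))
  # latitude: 3 codings x 3 subsets x (pooled + per-year);
  # longitude: 3 codings x 1 subset x (pooled + per-year);
  # year: 3 codings x 2 macro-area groups, pooled only
  expected_rows <- 3 * 3 * (1 + length(years)) + 3 * 1 * (1 + length(years)) +
    3 * 2
  expect_equal(nrow(bat), expected_rows)

  # synthetic North-to-South A cline: frequency rises southward, so the
  # latitude slope (north-positive degrees) is negative
  row <- bat[bat$coding == "contains-A" & bat$predictor == "latitude" &
               bat$subset == "Peninsula" & bat$period == "pooled", ]
  expect_true(row$converged)
  expect_lt(row$b1, 0)

  # all-identical patterns in a subset: degenerate, not an error
  mono <- make_samples(paste0("b", 1:60), 2020, "C",
                       latitude = runif(60, 44, 47), longitude = runif(60, 7, 13))
  bat2 <- run_cline_battery(mono, codings = "contains-A",
                            predictors = "latitude", per_year = FALSE)
  expect_true(all(bat2$status == "degenerate"))
})

test_that("year-predictor fits respect the per-cell sample threshold", {
  cfg <- tiny_config(seed = 37, n_beekeepers = 60)   # far below 100/cell
  d <- simulate_dataset(cfg)
  bat <- run_cline_battery(d, predictors = "year")
  expect_true(all(bat$status == "skipped"))
  bat2 <- run_cline_battery(d, predictors = "year", min_cell = 0)
  expect_true(any(bat2$status == "ok"))
})
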