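test_that("zero heterogeneity is detected exactly", {
  y <- rep(0.3, 12)
  v <- runif(12, 0.01, 0.05)
  expect_equal(reml_tau2(y, v), 0)
})

test_that("REML tau2 matches a grid-search maximiser of the likelihood", {
  withr::with_seed(67, {
    for (i in 1:20) {
      k <- sample(10:40, 1)
      tau2_true <- runif(1, 0, 0.1)
      v <- runif(k, 0.005, 0.05)
      groups <- sample(c("North", "South"), k, replace = TRUE)
      X <- model.matrix(~ 0 + groups)
      mu <- ifelse(groups == "North", 0.05, 0.15)
      y <- rnorm(k, mu, sqrt(tau2_true + v))
      got <- reml_tau2(y, v, X)
      want <- grid_reml(y, v, X)
      expect_lt(abs(got - want), 1e-6)
    }
  })
})

test_that("REML tau2 agrees with metafor on a moderated model", {
  skip_if_not_installed("metafor")
  withr::with_seed(71, {
    k <- 80
    area <- sample(c("North", "Central", "South"), k, replace = TRUE)
    v <- runif(k, 0.01, 0.08)
    y <- rnorm(k, ifelse(area == "North", 0, 0.2), sqrt(0.03 + v))
  })
  X <- model.matrix(~ 0 + area)
  ref <- metafor::rma(yi = y, vi = v, mods = ~ 0 + factor(area),
                      method = "REML", control = list(tol = 1e-10))
  expect_equal(reml_tau2(y, v, X), ref$tau2, tolerance = 1e-4)
})

test_that("pooling reduces to simple and inverse-variance means in edge cases", {
  # equal variances, single moderator level: pooled estimate = mean
  withr::with_seed(73, y <- rnorm(30, 0.1, 0.1))
  tr <- tibble::tibble(macro_region = "North", tau = y, var_tau = 0.02)
  fit <- fit_meta(tr)
  expect_equal(fit$coefficients$estimate, mean(y), tolerance = 1e-10)

  # tau2 = 0: exact fixed-effect inverse-variance pooling
  y0 <- rep(c(0.1, 0.1), 10) + rep(c(-0.001, 0.001), 10)
  v0 <- runif(20, 0.05, 0.2)
  tr0 <- tibble::tibble(macro_region = "North", tau = y0, var_tau = v0)
  fit0 <- fit_meta(tr0)
  expect_equal(fit0$tau2, 0)
  expect_equal(fit0$coefficients$estimate, sum(y0 / v0) / sum(1 / v0),
               tolerance = 1e-10)
})

test_that("the meta-analysis is scale-equivariant", {
  withr::with_seed(79, {
    tr <- tibble::tibble(
      macro_region = sample(c("North", "South", "Sicily"), 60, replace = TRUE),
      tau = rnorm(60, 0.1, 0.25),
      var_tau = runif(60, 0.02, 0.1)
    )
  })
  f1 <- fit_meta(tr)
  cc <- 3
  f2 <- fit_meta(dplyr::mutate(tr, tau = tau * cc, var_tau = var_tau * cc^2))
  expect_equal(f2$tau2, cc^2 * f1$tau2, tolerance = 1e-6)
  expect_equal(f2$coefficients$estimate, cc * f1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$se, cc * f1$coefficients$se, tolerance = 1e-6)
})

test_that("the returned tau2 is a local maximum of the restricted likelihood", {
  withr::with_seed(83, {
    v <- runif(40, 0.01, 0.05)
    y <- rnorm(40, 0.1, sqrt(0.04 + v))
  })
  X <- matrix(1, 40, 1)
  t2 <- reml_tau2(y, v, X)
  expect_gte(reml_loglik(t2, y, v, X), reml_loglik(0, y, v, X))
  expect_gte(reml_loglik(t2, y, v, X), reml_loglik(10 * t2 + 0.01, y, v, X))
})

test_that("confidence intervals are symmetric and cover known level means", {
  withr::with_seed(89, {
    hits <- matrix(NA, 100, 2)
    for (r in 1:100) {
      k <- 150
      tr <- tibble::tibble(
        macro_region = rep(c("North", "South"), each = k),
        var_tau = runif(2 * k, 0.02, 0.08)
      )
      tr$tau <- rnorm(2 * k, rep(c(0.2, -0.1), each = k),
                      sqrt(0.03 + tr$var_tau))
      fit <- fit_meta(tr)
      co <- fit$coefficients
      expect_equal(co$ci_hi - co$estimate, co$estimate - co$ci_lo,
                   tolerance = 1e-10)
      hits[r, ] <- c(co$ci_lo[co$level == "North"] <= 0.2 &
                       co$ci_hi[co$level == "North"] >= 0.2,
                     co$ci_lo[co$level == "South"] <= -0.1 &
                       co$ci_hi[co$level == "South"] >= -0.1)
    }
  })
  expect_gte(mean(hits[, 1]), 0.90)
  expect_gte(mean(hits[, 2]), 0.90)
})

test_that("moderator schemes, flags and structural invariants hold", {
  withr::with_seed(97, {
    tr <- tibble::tibble(
      macro_region = c(rep("North", 20), rep("Central", 15), rep("South", 12),
                       rep("Sicily", 5), "Sardinia"),
      tau = rnorm(53, 0.05, 0.2),
      var_tau = runif(53, 0.02, 0.08),
      degenerate = c(rep(FALSE, 50), rep(TRUE, 3))
    )
  })
  f5 <- fit_meta(tr, scheme = "areas")
  expect_setequal(f5$coefficients$level,
                  c("North", "Central", "South", "Sicily", "Sardinia"))
  f4 <- fit_meta(tr, scheme = "macro_areas")
  expect_setequal(f4$coefficients$level,
                  c("North", "Central-South", "Sicily", "Sardinia"))
  expect_equal(f4$coefficients$k[f4$coefficients$level == "Central-South"], 27L)
  # forest counts sum to the input count
  expect_equal(sum(f4$coefficients$k), nrow(tr))
  expect_gte(f4$tau2, 0)
  # single-estimate level: SE from its own v_i + tau2, flagged
  sard <- f5$coefficients[f5$coefficients$level == "Sardinia", ]
  expect_true(sard$single_estimate)
  expect_equal(sard$se, sqrt(tr$var_tau[53] + f5$tau2), tolerance = 1e-8)
  # degenerate exclusion flag
  fx <- fit_meta(tr, exclude_degenerate = TRUE)
  expect_equal(fx$k, 50L)
  # tidy/glance surface
  expect_equal(tidy(f4), f4$coefficients)
  expect_equal(glance(f4)$tau2, f4$tau2)
})
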