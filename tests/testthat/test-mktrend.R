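test_that("diversity series are union cardinalities per beekeeper-year", {
  s <- make_samples("b1", c(2018, 2019, 2020, 2021), c("C", "C", "AC", "ACM"))
  ser <- build_diversity_series(s)
  expect_equal(ser$diversity, c(1L, 1L, 2L, 3L))
  expect_true(all(ser$trend_eligible))

  # union across same-year samples: {C} and {A,C} in one year scores 2
  s2 <- make_samples("b2", c(2018, 2018, 2019, 2020, 2021),
                     c("C", "AC", "C", "C", "C"))
  ser2 <- build_diversity_series(s2)
  expect_equal(ser2$diversity[ser2$year == 2018], 2L)

  # three observed years: censused but not trend-eligible
  s3 <- make_samples("b3", 2018:2020, "C")
  ser3 <- build_diversity_series(s3)
  expect_equal(nrow(ser3), 3L)
  expect_false(any(ser3$trend_eligible))
})

test_that("diversity equals brute-force lineage unions on random tables", {
  s <- random_samples(25, seed = 41)
  ser <- build_diversity_series(s)
  for (r in sample(nrow(ser), 20)) {
    sub <- s[s$beekeeper_id == ser$beekeeper_id[r] & s$year == ser$year[r], ]
    expect_equal(ser$diversity[r],
                 length(unique(unlist(strsplit(sub$pattern, "")))))
  }
})

test_that("Kendall S, tau and var_S match exhaustive pair enumeration", {
  expect_equal(kendall_S_tau(c(1, 2, 3, 4))[c("S", "tau")],
               list(S = 6, tau = 1))
  # exhaustive over all {1,2,3}-valued series of length 2..6
  for (n in 2:6) {
    grids <- as.matrix(expand.grid(rep(list(1:3), n)))
    for (r in seq_len(nrow(grids))) {
      x <- unname(grids[r, ])
      got <- kendall_S_tau(x)
      want <- brute_kendall(x)
      expect_identical(got$S, want$S)
      expect_equal(got$tau, want$tau, tolerance = 1e-12)
      expect_equal(got$var_S, want$var_S, tolerance = 1e-12)
    }
  }
})

test_that("tau agrees with the reference rank correlation when defined", {
  withr::with_seed(43, {
    for (i in 1:20) {
      x <- sample(1:3, 6, replace = TRUE)
      if (length(unique(x)) == 1) next
      expect_equal(kendall_S_tau(x)$tau,
                   suppressWarnings(cor(seq_along(x), x, method = "kendall")),
                   tolerance = 1e-12)
    }
  })
})

test_that("var_S formula matches simulation for continuous series", {
  withr::with_seed(47, {
    S_vals <- replicate(1e4, kendall_S_tau(rnorm(10))$S)
  })
  expect_equal(var(S_vals), kendall_S_tau(rnorm(10))$var_S, tolerance = 0.02)
})

test_that("Kendall statistics are antisymmetric and rank-invariant", {
  withr::with_seed(53, {
    for (i in 1:20) {
      x <- sample(1:3, 7, replace = TRUE)
      fwd <- kendall_S_tau(x); rev_ <- kendall_S_tau(rev(x))
      expect_identical(rev_$S, -fwd$S)
      expect_equal(rev_$tau, -fwd$tau, tolerance = 1e-12)
      expect_equal(rev_$var_S, fwd$var_S)
      # strictly increasing transforms leave everything unchanged
      tr <- kendall_S_tau(exp(2 * x))
      expect_identical(tr$S, fwd$S)
      expect_equal(tr$tau, fwd$tau)
      expect_equal(tr$var_S, fwd$var_S)
    }
  })
})

test_that("the autocorrelation correction is 1 when no lag is significant", {
  # rank lag-1 autocorrelation of (1,3,2,4) is -0.35, below the 5% cutoff
  mm <- mmk_corrected_variance(c(1, 3, 2, 4))
  expect_equal(mm$correction, 1)
  expect_equal(mm$var_S_star, kendall_S_tau(c(1, 3, 2, 4))$var_S)
  expect_error(mmk_corrected_variance(c(1, 2, 3)), "length >= 4")
})

test_that("the correction is calibrated on white noise and reacts to AR(1)", {
  withr::with_seed(59, {
    wn <- replicate(1000, mmk_corrected_variance(rnorm(50))$correction)
  })
  expect_lt(abs(mean(wn) - 1), 0.1)
  withr::with_seed(61, {
    ar <- replicate(300, {
      x <- as.numeric(arima.sim(list(ar = 0.6), 50))
      mmk_corrected_variance(x)$correction
    })
  })
  expect_gt(median(ar), 1)
})

test_that("mk_test combines score, correction and continuity correction", {
  res <- mk_test(c(1, 2, 3, 4, 5))
  expect_equal(res$tau, 1)
  expect_gt(res$z, 0)
  expect_equal(res$z, (res$S - 1) / sqrt(res$var_S_star))
  expect_equal(res$var_tau, res$var_S_star / (5 * 4 / 2)^2)

  rev_res <- mk_test(c(5, 4, 3, 2, 1))
  expect_equal(rev_res$S, -res$S)
  expect_equal(rev_res$tau, -res$tau)
  expect_equal(rev_res$var_S_star, res$var_S_star)

  # constant series: degenerate but still consumable downstream
  con <- mk_test(c(2, 2, 2, 2))
  expect_true(con$degenerate)
  expect_equal(con$tau, 0)
  expect_equal(con$var_tau, (4 * 3 * 13 / 18) / (4 * 3 / 2)^2)
  expect_error(mk_test(c(1, 2, 3)), "length >= 4")
})

test_that("mk_trend keeps only beekeepers with enough observed years", {
  s <- dplyr::bind_rows(
    make_samples("long", 2018:2023, c("C", "C", "AC", "AC", "ACM", "ACM")),
    make_samples("short", 2018:2020, "C")
  )
  tr <- mk_trend(s)
  expect_equal(tr$beekeeper_id, "long")
  expect_gt(tr$tau, 0)
})
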