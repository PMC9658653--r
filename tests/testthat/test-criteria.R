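test_that("the frequentist precision benchmark matches hand arithmetic", {
  expect_equal(frequentist_n(0.2625, 0.2), 75L)
  expect_equal(frequentist_n(0.5, 0.2), 97L)
  expect_equal(frequentist_n(0.26, 0.2), 74L)
  expect_error(frequentist_n(0), "must be in")
})

test_that("the worst-outcome subset follows the piecewise rule", {
  expect_equal(worst_outcome_subset(45, 8, 22), c(29L, 30L))
  expect_equal(worst_outcome_subset(10, 8, 22), 10L)
  expect_equal(worst_outcome_subset(46, 8, 22), 30L)
  expect_error(worst_outcome_subset(10, -1, 5), "positive")
  # non-integer prior counts: the two bracketing integers are evaluated
  expect_equal(worst_outcome_subset(60, 4.5, 11.5), c(33L, 34L))
})

test_that("predictive resampling of expected successes is calibrated", {
  c1 <- resample_expected_successes(beta_prior(8, 22), 45, seed = 99)
  expect_identical(c1, resample_expected_successes(beta_prior(8, 22), 45,
                                                   seed = 99))
  tight <- beta_prior(2600, 7400)  # concentrated near 0.26
  expect_lt(abs(resample_expected_successes(tight, 100, seed = 3) - 26), 2.5)
  meds <- vapply(1:10, function(s)
    resample_expected_successes(beta_prior(1, 1), 100, seed = s), 0)
  expect_lt(abs(median(meds) - 50), 3)
})

test_that("search bounds bracket half to one-and-a-half benchmarks", {
  expect_equal(bssd:::search_bounds(75), c(38L, 112L))
  expect_equal(bssd:::search_bounds(1), c(1L, 1L))
})

test_that("ACC and ALC searches agree with brute-force enumeration on toy cases", {
  # all data outcomes enumerated, every interval placement grid-searched
  pr <- beta_prior(2, 2)
  for (l in c(0.45, 0.6)) {
    ref <- bf_first_n(2, 2, "acc", l, 0.8, placement = "optimal")
    got <- sample_size(pr, "acc", l = l, coverage = 0.8,
                       placement = "optimal", n_range = c(1, 12))
    expect_equal(got$n_opt, ref)
    ref_a <- bf_first_n(2, 2, "acc", l, 0.8, placement = "hpd")
    got_a <- sample_size(pr, "acc", l = l, coverage = 0.8,
                         placement = "hpd", n_range = c(1, 12))
    expect_equal(got_a$n_opt, ref_a)
  }
  ref_l <- bf_first_n(2, 2, "alc", 0.55, 0.9, n_max = 12)
  got_l <- sample_size(pr, "alc", l = 0.55, coverage = 0.9,
                       n_range = c(1, 12))
  expect_equal(got_l$n_opt, ref_l)
})

test_that("trivial lengths collapse the search to the lower bound", {
  got <- sample_size(beta_prior(3, 7), "acc", l = 0.95, coverage = 0.9,
                     n_range = c(4, 30))
  expect_equal(got$n_opt, 4L)
  got2 <- sample_size(beta_prior(3, 7), "alc", l = 0.99, coverage = 0.5,
                      n_range = c(2, 30))
  expect_equal(got2$n_opt, 2L)
})

test_that("window search equals an exhaustive scan for a monotone criterion", {
  a <- sample_size(beta_prior(8, 22), "alc")
  b <- sample_size(beta_prior(8, 22), "alc", n_range = c(1, 200))
  expect_equal(a$n_opt, b$n_opt)
  expect_equal(a$n_opt, 42L)
})

test_that("criterion curves are monotone in n", {
  pr <- beta_prior(8, 22)
  ns <- 38:50
  covs <- vapply(ns, function(n) average_coverage(pr, n, 0.2, 0.95), 0)
  lens <- vapply(ns, function(n) average_length(pr, n, 0.95), 0)
  expect_true(all(diff(covs) > 0))
  expect_true(all(diff(lens) < 0))
  bp <- bspline_prior(quantile(uti_panel()), 4, 1)
  ns2 <- c(40L, 50L, 60L, 70L)
  covs2 <- vapply(ns2, function(n) average_coverage(bp, n, 0.2, 0.95), 0)
  lens2 <- vapply(ns2, function(n) average_length(bp, n, 0.95), 0)
  expect_true(all(diff(covs2) > 0))
  expect_true(all(diff(lens2) < 0))
})

test_that("for a uniform prior the formula subset attains the worst coverage", {
  pr <- beta_prior(1, 1)
  for (n in c(10L, 37L, 85L, 150L)) {
    full <- worst_coverage(pr, n, 0.2, 0.95, placement = "optimal",
                           woc_space = "full")
    form <- worst_coverage(pr, n, 0.2, 0.95, placement = "optimal",
                           woc_space = "formula")
    expect_equal(as.numeric(form), as.numeric(full), tolerance = 1e-10)
  }
})

test_that("woc variants are ordered: full is the most conservative", {
  pr <- beta_prior(8, 22)
  n <- 60L
  v_full <- as.numeric(worst_coverage(pr, n, woc_space = "full"))
  v_form <- as.numeric(worst_coverage(pr, n, woc_space = "formula"))
  v_band <- as.numeric(worst_coverage(pr, n, woc_space = "predictive-band"))
  expect_lte(v_full, v_form + 1e-12)
  expect_lte(v_full, v_band + 1e-12)
})

test_that("an unattainable criterion fails loudly after bound expansion", {
  expect_error(
    sample_size(beta_prior(1, 1), "alc", l = 0.01, coverage = 0.99,
                n_range = c(2, 6)),
    "not met")
})

test_that("non-unimodal priors are accepted with a warning", {
  pr <- bspline_prior(quantile(uti_panel()), 4, 0.15)
  expect_warning(fit <- sample_size(pr, "alc", n_range = c(40, 80)),
                 "unimodal")
  expect_true(fit$n_opt >= 40 && fit$n_opt <= 80)
})
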