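test_that("Beta posteriors are conjugate and no data returns the prior", {
  p <- posterior(beta_prior(8, 22), 10, 3)
  expect_equal(c(p$alpha, p$beta), c(11, 29))
  p0 <- posterior(beta_prior(8, 22), 0, 0)
  th <- seq(0.01, 0.99, by = 0.01)
  expect_equal(p0$density(th), dbeta(th, 8, 22), tolerance = 1e-12)
  expect_error(posterior(beta_prior(2, 2), 5, 7), "0 <= x <= n")
})

test_that("the quadrature path matches the conjugate closed form", {
  set.seed(42)
  for (i in 1:6) {
    a <- runif(1, 0.8, 12); b <- runif(1, 0.8, 12)
    n <- sample(5:40, 1); x <- sample(0:n, 1)
    pn <- posterior(beta_prior(a, b), n, x, method = "numeric")
    th <- seq(0.001, 0.999, length.out = 400)
    expect_lt(max(abs(pn$density(th) - dbeta(th, a + x, b + n - x))), 1e-6)
    expect_lt(max(abs(pn$cdf(th) - pbeta(th, a + x, b + n - x))), 2e-5)
    pr <- predictive(beta_prior(a, b), n, method = "numeric")
    expect_lt(max(abs(pr$pmf - predictive(beta_prior(a, b), n)$pmf)), 1e-8)
  }
})

test_that("numeric posteriors of a spline prior are proper distributions", {
  pr <- bspline_prior(quantile(uti_panel()), 4, 1)
  p <- posterior(pr, 20, 5)
  expect_equal(integrate(p$density, 0, 1, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  expect_equal(p$cdf(1), 1, tolerance = 1e-9)
  expect_equal(p$cdf(0), 0, tolerance = 1e-9)
  th <- seq(0, 1, length.out = 301)
  expect_true(all(diff(p$cdf(th)) >= -1e-10))
})

test_that("predictive distributions normalize and match known closed forms", {
  expect_equal(predictive(beta_prior(1, 1), 5)$pmf, rep(1 / 6, 6),
               tolerance = 1e-12)
  expect_equal(predictive(beta_prior(8, 22), 2)$pmf[1], 506 / 930,
               tolerance = 1e-12)
  pr <- bspline_prior(quantile(uti_panel()), 4, 0.5)
  pmf <- predictive(pr, 17)$pmf
  expect_true(all(pmf >= 0))
  expect_equal(sum(pmf), 1, tolerance = 1e-8)
})

test_that("predictive pmf agrees with two-stage Monte-Carlo sampling", {
  pr <- bspline_prior(quantile(uti_panel()), 4, 1)
  n <- 12
  pmf <- predictive(pr, n)$pmf
  N <- 1e5
  draws <- with(list(), {
    set.seed(2024)
    th <- rprior(pr, N)
    rbinom(N, n, th)
  })
  obs <- tabulate(draws + 1L, nbins = n + 1L) / N
  se <- sqrt(pmf * (1 - pmf) / N)
  expect_true(all(abs(obs - pmf) <= 3 * se + 1e-12))
})

test_that("fixed-coverage HPD intervals match known Beta geometry", {
  sym <- hpd_fixed_coverage(posterior(beta_prior(2, 2), 0, 0), 0.95)
  expect_equal(sym$lower + sym$length / 2, 0.5, tolerance = 1e-6)

  mono <- hpd_fixed_coverage(posterior(beta_prior(1, 76), 0, 0), 0.95)
  expect_equal(mono$lower, 0, tolerance = 1e-9)
  expect_equal(mono$length, 1 - 0.05^(1 / 76), tolerance = 1e-7)
  expect_true(mono$is_hpd)

  full <- hpd_fixed_coverage(posterior(beta_prior(3, 5), 4, 2), 1)
  expect_equal(c(full$lower, full$length, full$coverage), c(0, 1, 1))
})

test_that("fixed-length HPD intervals match known Beta geometry", {
  mono <- hpd_fixed_length(posterior(beta_prior(1, 76), 0, 0), 0.1)
  expect_equal(mono$lower, 0, tolerance = 1e-9)
  expect_equal(mono$coverage, 1 - 0.9^76, tolerance = 1e-9)

  sym <- hpd_fixed_length(posterior(beta_prior(47, 47), 0, 0), 0.2)
  expect_equal(sym$lower, 0.4, tolerance = 1e-4)
  expect_true(sym$is_hpd)

  full <- hpd_fixed_length(posterior(beta_prior(3, 5), 4, 2), 1)
  expect_equal(full$coverage, 1)
})

test_that("both HPD searches agree with brute-force grid enumeration", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 1, 15); b <- runif(1, 1, 15)
    n <- sample(0:30, 1); x <- if (n > 0) sample(0:n, 1) else 0
    post <- posterior(beta_prior(a, b), n, x)
    l <- runif(1, 0.08, 0.5)
    got <- hpd_fixed_length(post, l)
    ref <- bf_fixed_length(a + x, b + n - x, l)
    expect_lt(abs(got$coverage - ref$coverage), 1e-4)
    expect_lt(abs(got$lower - ref$lower), 2e-4)
    cv <- runif(1, 0.5, 0.99)
    got2 <- hpd_fixed_coverage(post, cv)
    ref2 <- bf_fixed_coverage(a + x, b + n - x, cv)
    expect_lt(abs(got2$length - ref2$length), 1e-4)
    expect_lt(abs(got2$lower - ref2$lower), 2e-4)
  }
})

test_that("coverage grows with length and length grows with coverage", {
  post <- posterior(beta_prior(6, 14), 25, 8)
  ls <- seq(0.05, 0.6, by = 0.05)
  covs <- vapply(ls, function(l) hpd_fixed_length(post, l)$coverage, 0)
  expect_true(all(diff(covs) >= 0))
  cvs <- seq(0.5, 0.99, by = 0.05)
  lens <- vapply(cvs, function(cv) hpd_fixed_coverage(post, cv)$length, 0)
  expect_true(all(diff(lens) >= 0))
})

test_that("severely multimodal numeric posteriors are refused", {
  # the sparse-knot informative fit with no data keeps its two real modes
  pr <- bspline_prior(quantile(uti_panel()), 4, 0.15)
  post <- posterior(pr, 0, 0)
  expect_error(hpd_fixed_length(post, 0.2), "multimodal")
  expect_error(hpd_fixed_coverage(post, 0.95), "multimodal")
})
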