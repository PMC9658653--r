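# Independent brute-force oracles used across the suite.  They share no code
# with the package internals: plain grid enumeration over interval
# placements using the Beta special functions.

# fixed length l: maximal-coverage placement by exhaustive grid search
bf_fixed_length <- function(a, b, l, step = 1e-4) {
  lo <- seq(0, 1 - l, by = step)
  cov <- pbeta(lo + l, a, b) - pbeta(lo, a, b)
  i <- which.max(cov)
  list(lower = lo[i], coverage = cov[i])
}

# fixed coverage: minimal-length interval by exhaustive grid on tail mass
bf_fixed_coverage <- function(a, b, coverage, step = 1e-4) {
  t <- seq(0, 1 - coverage, by = step * (1 - coverage) * 10)
  len <- qbeta(t + coverage, a, b) - qbeta(t, a, b)
  i <- which.min(len)
  list(lower = qbeta(t[i], a, b), length = len[i])
}

# anchored coverage: length-l interval at the lower bound of the
# minimal-length interval of the given mass
bf_anchored_cov <- function(a, b, l, coverage, step = 1e-4) {
  L <- bf_fixed_coverage(a, b, coverage, step)$lower
  pbeta(min(L + l, 1), a, b) - pbeta(L, a, b)
}

bf_bb_pmf <- function(a, b, n) {
  xs <- 0:n
  p <- choose(n, xs) * beta(a + xs, b + n - xs) / beta(a, b)
  p / sum(p)
}

# brute-force per-n criterion values for small Beta problems
bf_avg_coverage <- function(a, b, n, l, coverage = 0.95,
                            placement = "optimal", step = 1e-4) {
  w <- bf_bb_pmf(a, b, n)
  covs <- vapply(0:n, function(x) {
    if (placement == "optimal")
      bf_fixed_length(a + x, b + n - x, l, step)$coverage
    else
      bf_anchored_cov(a + x, b + n - x, l, coverage, step)
  }, 0)
  sum(w * covs)
}

bf_avg_length <- function(a, b, n, coverage, step = 1e-4) {
  w <- bf_bb_pmf(a, b, n)
  lens <- vapply(0:n, function(x)
    bf_fixed_coverage(a + x, b + n - x, coverage, step)$length, 0)
  sum(w * lens)
}

# first n in 1..n_max whose brute-force criterion value passes
bf_first_n <- function(a, b, criterion, l, coverage, n_max = 12,
                       placement = "optimal") {
  for (n in 1:n_max) {
    v <- if (criterion == "alc") bf_avg_length(a, b, n, coverage)
         else bf_avg_coverage(a, b, n, l, coverage, placement)
    ok <- if (criterion == "alc") v <= l else v >= coverage
    if (ok) return(n)
  }
  NA_integer_
}

# the full scenario table is used by several tests; compute it once
.cache <- new.env(parent = emptyenv())
cached_scenarios <- function() {
  if (is.null(.cache$tab))
    .cache$tab <- suppressWarnings(ssd_scenarios(uti_panel()))
  .cache$tab
}
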