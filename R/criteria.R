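# Sample size criteria ---------------------------------------------------

#' Frequentist precision benchmark
#'
#' One-arm precision sample size for a binomial proportion: the smallest `n`
#' whose two-sided Wald confidence interval at the given level has total
#' length at most `l`, i.e. `n = ceiling(z^2 p (1 - p) / (l / 2)^2)`.
#'
#' @param p expected proportion in (0, 1).
#' @param l total confidence interval length.
#' @param level confidence level (default 0.95).
#' @return An integer sample size.
#' @examples
#' frequentist_n(0.2625, 0.2)  # 75
#' @export
frequentist_n <- function(p, l = 0.2, level = 0.95) {
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  as.integer(ceiling(round(z^2 * p * (1 - p) / (l / 2)^2, 9)))
}

# fast Beta-posterior interval primitives (closed-form path) --------------

bb_pmf <- function(a, b, n) {
  xs <- 0:n
  p <- exp(lchoose(n, xs) + lbeta(a + xs, b + n - xs) - lbeta(a, b))
  p / sum(p)
}

# lower tail mass of the minimal-length interval with given mass
beta_hpd_tail <- function(a, b, coverage) {
  g <- function(t) qbeta(t + coverage, a, b) - qbeta(t, a, b)
  opt <- optimize(g, c(0, 1 - coverage), tol = 1e-12)
  cands <- c(0, opt$minimum, 1 - coverage)
  lens <- vapply(cands, g, 0)
  cands[which.min(lens)]
}

beta_min_len <- function(a, b, coverage) {
  t0 <- beta_hpd_tail(a, b, coverage)
  qbeta(t0 + coverage, a, b) - qbeta(t0, a, b)
}

beta_len_cov <- function(a, b, l, coverage, placement) {
  if (placement == "optimal") {
    f <- function(lo) pbeta(lo + l, a, b) - pbeta(lo, a, b)
    opt <- optimize(f, c(0, 1 - l), maximum = TRUE, tol = 1e-10)
    return(max(opt$objective, f(0), f(1 - l)))
  }
  L <- qbeta(beta_hpd_tail(a, b, coverage), a, b)
  pbeta(min(L + l, 1), a, b) - pbeta(L, a, b)
}

# numeric-posterior family (generic-prior path) ---------------------------
# one shot per n: kernel matrix over a fixed grid, column-wise cumulative
# trapezoid CDFs and the normalized predictive pmf

post_family <- function(prior, n, grid_n = 4000L) {
  dom <- if (inherits(prior, "bspline_prior")) prior$basis$domain else c(0, 1)
  brk <- if (inherits(prior, "bspline_prior"))
    unique(prior$basis$knots) else dom
  th <- sort(unique(c(seq(dom[1], dom[2], length.out = grid_n + 1L), brk)))
  G <- length(th)
  f <- dprior(prior, th)
  xs <- 0:n
  lt <- log(th); l1t <- log1p(-th)
  lt[!is.finite(lt)] <- 0; l1t[!is.finite(l1t)] <- 0
  M <- exp(outer(lt, xs) + outer(l1t, n - xs))     # G x (n+1) kernel
  if (th[1] <= 0) M[1, ] <- as.numeric(xs == 0)
  if (th[G] >= 1) M[G, ] <- as.numeric(xs == n)
  M <- M * f
  dth <- diff(th)
  avg <- (M[-1, , drop = FALSE] + M[-G, , drop = FALSE]) / 2
  cum <- apply(avg * dth, 2, cumsum)
  tot <- cum[G - 1L, ]
  cdf <- rbind(0, sweep(cum, 2, tot, "/"))
  pmf <- exp(lchoose(n, xs)) * tot
  list(th = th, cdf = cdf, pmf = pmf / sum(pmf), n = n)
}

# linear interpolation of a tabulated monotone CDF
interp_cdf <- function(th, cdfv, x) {
  G <- length(th)
  x <- pmin(pmax(x, th[1]), th[G])
  j <- pmin(pmax(findInterval(x, th), 1L), G - 1L)
  den <- th[j + 1L] - th[j]
  w <- ifelse(den > 0, (x - th[j]) / den, 0)
  pmin(pmax(cdfv[j] + w * (cdfv[j + 1L] - cdfv[j]), 0), 1)
}

# minimal interval length at given mass, from a tabulated CDF; also returns
# the achieving lower bound
grid_min_len <- function(th, cdfv, coverage) {
  G <- length(th)
  ok <- which(cdfv <= 1 - coverage + 1e-12)
  tv <- cdfv[ok] + coverage
  j <- pmin(pmax(findInterval(tv, cdfv), 1L), G - 1L)
  den <- cdfv[j + 1L] - cdfv[j]
  w <- ifelse(den > 0, (tv - cdfv[j]) / den, 1)
  upper <- th[j] + pmin(pmax(w, 0), 1) * (th[j + 1L] - th[j])
  lens <- upper - th[ok]
  i <- which.min(lens)
  c(len = lens[i], lower = th[ok[i]])
}

grid_len_cov <- function(th, cdfv, l, coverage, placement) {
  if (placement == "optimal") {
    cu <- interp_cdf(th, cdfv, th + l)
    return(max(cu - cdfv))
  }
  L <- grid_min_len(th, cdfv, coverage)[["lower"]]
  interp_cdf(th, cdfv, L + l) - interp_cdf(th, cdfv, L)
}

# per-n criterion diagnostics ---------------------------------------------

#' Per-sample-size design diagnostics
#'
#' The predictive-weighted average coverage of fixed-length intervals
#' (`average_coverage`), the predictive-weighted average length of
#' fixed-coverage HPD intervals (`average_length`), and the minimum
#' fixed-length coverage over a worst-outcome data subset
#' (`worst_coverage`), all for a given prior and sample size.  These are the
#' quantities the ACC/ALC/WOC searches in [sample_size()] threshold.
#'
#' @param prior a prior model.
#' @param n sample size.
#' @param l HPD interval length (probability scale).
#' @param coverage credibility level.
#' @param placement placement rule for the fixed-length interval:
#'   `"hpd"` anchors it at the lower bound of the `coverage`-level HPD
#'   interval (the reference procedure used for the package's reported
#'   designs); `"optimal"` maximizes its coverage.
#' @param woc_space which data subset the worst case is taken over:
#'   `"formula"` (the closed-form worst-outcome candidates), `"full"` (all
#'   `x = 0..n`), or `"predictive-band"` (the central 95% predictive mass).
#' @param cd optional `c(successes, failures)` pair of prior expected counts
#'   for the worst-outcome formula; defaults to the Beta shapes for a Beta
#'   prior, or prior-predictive resampling otherwise.
#' @param seed integer seed for the worst-outcome resampling.
#' @param draws number of resampling draws.
#' @param grid_n grid resolution for numeric posteriors.
#' @return A scalar diagnostic; `worst_coverage` carries the evaluated
#'   subset as attribute `"x_star"` (and `"c"`, `"d"` when the formula
#'   subset is used).
#' @name design-diagnostics
#' @examples
#' average_coverage(beta_prior(8, 22), 43, l = 0.2)
#' average_length(beta_prior(8, 22), 42)
#' @export
average_coverage <- function(prior, n, l = 0.2, coverage = 0.95,
                             placement = c("hpd", "optimal"),
                             grid_n = 4000L) {
  placement <- match.arg(placement)
  if (inherits(prior, "beta_prior")) {
    a <- prior$alpha; b <- prior$beta
    w <- bb_pmf(a, b, n)
    covs <- vapply(0:n, function(x)
      beta_len_cov(a + x, b + n - x, l, coverage, placement), 0)
    return(sum(w * covs))
  }
  fam <- post_family(prior, n, grid_n)
  covs <- vapply(seq_len(n + 1L), function(i)
    grid_len_cov(fam$th, fam$cdf[, i], l, coverage, placement), 0)
  sum(fam$pmf * covs)
}

#' @rdname design-diagnostics
#' @export
average_length <- function(prior, n, coverage = 0.95, grid_n = 4000L) {
  if (inherits(prior, "beta_prior")) {
    a <- prior$alpha; b <- prior$beta
    w <- bb_pmf(a, b, n)
    lens <- vapply(0:n, function(x)
      beta_min_len(a + x, b + n - x, coverage), 0)
    return(sum(w * lens))
  }
  fam <- post_family(prior, n, grid_n)
  lens <- vapply(seq_len(n + 1L), function(i)
    grid_min_len(fam$th, fam$cdf[, i], coverage)[["len"]], 0)
  sum(fam$pmf * lens)
}

#' Worst-outcome data subset
#'
#' Closed-form candidates for the number of successes whose posterior
#' carries the lowest fixed-length coverage, given prior expected successes
#' `c` and failures `d`: for `n <= |d - c|` the subset is `{n}`; otherwise
#' the integer(s) bracketing `(n + c + d) / 2 - c`, clipped to `[0, n]`.
#'
#' @param n sample size.
#' @param c,d prior expected successes and failures (positive).
#' @return Integer vector of worst-outcome candidates.
#' @examples
#' worst_outcome_subset(45, 8, 22)  # 29 30
#' worst_outcome_subset(10, 8, 22)  # 10
#' @export
worst_outcome_subset <- function(n, c, d) {
  if (c <= 0 || d <= 0) stop("'c' and 'd' must be positive", call. = FALSE)
  if (n <= abs(d - c)) return(as.integer(n))
  xc <- (n + c + d) / 2 - c
  sort(unique(as.integer(pmin(pmax(c(floor(xc), ceiling(xc)), 0), n))))
}

#' Prior expected successes by predictive resampling
#'
#' Draws `draws` proportions from the prior, simulates one binomial
#' experiment of size `n` for each, and returns the median success count.
#' Deterministic given `seed`.
#'
#' @inheritParams design-diagnostics
#' @return The median simulated success count.
#' @examples
#' resample_expected_successes(beta_prior(8, 22), 45, seed = 1)
#' @export
resample_expected_successes <- function(prior, n, draws = 1000L, seed = 1L) {
  if (draws < 1) stop("'draws' must be at least 1", call. = FALSE)
  with_seed(seed, {
    th <- rprior(prior, draws)
    median(rbinom(draws, n, th))
  })
}

#' @rdname design-diagnostics
#' @export
worst_coverage <- function(prior, n, l = 0.2, coverage = 0.95,
                           placement = c("hpd", "optimal"),
                           woc_space = c("formula", "full",
                                         "predictive-band"),
                           cd = NULL, seed = 1L, draws = 1000L,
                           grid_n = 4000L) {
  placement <- match.arg(placement)
  woc_space <- match.arg(woc_space)
  cc <- dd <- NULL
  if (woc_space == "formula") {
    if (!is.null(cd)) {
      cc <- cd[1]; dd <- cd[2]
    } else if (inherits(prior, "beta_prior")) {
      cc <- prior$alpha; dd <- prior$beta
    } else {
      cc <- resample_expected_successes(prior, n, draws, seed)
      dd <- n - cc
      if (cc <= 0) cc <- 0.5
      if (dd <= 0) dd <- 0.5
    }
    xs <- worst_outcome_subset(n, cc, dd)
  } else if (woc_space == "full") {
    xs <- 0:n
  } else {
    pmf <- predictive(prior, n)$pmf
    cum <- cumsum(pmf)
    xs <- (which(cum >= 0.025)[1] - 1L):(which(cum >= 0.975)[1] - 1L)
  }
  if (inherits(prior, "beta_prior")) {
    a <- prior$alpha; b <- prior$beta
    covs <- vapply(xs, function(x)
      beta_len_cov(a + x, b + n - x, l, coverage, placement), 0)
  } else {
    fam <- post_family(prior, n, grid_n)
    covs <- vapply(xs, function(x)
      grid_len_cov(fam$th, fam$cdf[, x + 1L], l, coverage, placement), 0)
  }
  out <- min(covs)
  attr(out, "x_star") <- xs[which.min(covs)]
  attr(out, "x_star_set") <- xs
  if (!is.null(cc)) { attr(out, "c") <- cc; attr(out, "d") <- dd }
  out
}

# the search policy -------------------------------------------------------

search_bounds <- function(n_hat) {
  c(max(1L, as.integer(ceiling(0.5 * n_hat))),
    as.integer(floor(1.5 * n_hat)))
}

#' Bayesian sample size determination
#'
#' The core search: the smallest sample size in a window around the
#' frequentist precision benchmark meeting the chosen criterion.
#' \describe{
#'   \item{`"acc"`}{average coverage criterion -- with interval length fixed
#'     at `l`, the predictive-weighted average posterior coverage must reach
#'     `coverage`;}
#'   \item{`"alc"`}{average length criterion -- with coverage fixed, the
#'     predictive-weighted average HPD length must not exceed `l`;}
#'   \item{`"woc"`}{worst outcome criterion -- the fixed-length coverage must
#'     reach `coverage` for every worst-outcome candidate.}
#' }
#' Any unimodal prior model is accepted: Beta posteriors use exact special
#' functions, other priors a fine-grid numeric posterior.  The search scans
#' ascending integers in `[ceiling(0.5 n_hat), floor(1.5 n_hat)]` where
#' `n_hat` is the frequentist benchmark (overridable via `n_range`); if the
#' criterion is not met the upper bound is doubled once and the result
#' flagged.
#'
#' @inheritParams design-diagnostics
#' @param criterion `"acc"`, `"alc"` or `"woc"`.
#' @param n_range optional integer vector `c(lower, upper)` overriding the
#'   benchmark-centred search window.
#' @param expand double the upper bound once if the criterion is unmet.
#' @param benchmark_p proportion used for the frequentist benchmark;
#'   defaults to the prior mean.
#' @return An object of class `ssd`: the optimal size `n_opt`, the per-`n`
#'   diagnostic `curve`, the frequentist benchmark, the search bounds, and
#'   the worst-outcome bookkeeping for `"woc"`.
#' @examples
#' fit <- sample_size(beta_prior(8, 22), "acc", l = 0.2, coverage = 0.95)
#' fit$n_opt  # 43
#' @export
sample_size <- function(prior, criterion = c("acc", "alc", "woc"),
                        l = 0.2, coverage = 0.95,
                        placement = c("hpd", "optimal"),
                        woc_space = c("formula", "full", "predictive-band"),
                        n_range = NULL, expand = TRUE, seed = 1L,
                        draws = 1000L, cd = NULL, benchmark_p = NULL,
                        grid_n = 4000L) {
  criterion <- match.arg(criterion)
  placement <- match.arg(placement)
  woc_space <- match.arg(woc_space)
  if (l <= 0 || l >= 1 || coverage <= 0 || coverage >= 1)
    stop("need 0 < l < 1 and 0 < coverage < 1", call. = FALSE)
  if (!is_unimodal(prior))
    warning("prior is not strictly unimodal; intervals are computed as ",
            "narrowest intervals of the given mass", call. = FALSE)
  p0 <- if (is.null(benchmark_p)) prior_mean(prior) else benchmark_p
  n_hat <- frequentist_n(p0, l, coverage)
  bounds <- if (is.null(n_range)) search_bounds(n_hat)
            else as.integer(n_range)
  value_at <- function(n) switch(criterion,
    acc = average_coverage(prior, n, l, coverage, placement, grid_n),
    alc = average_length(prior, n, coverage, grid_n),
    woc = as.numeric(worst_coverage(prior, n, l, coverage, placement,
                                    woc_space, cd, seed, draws, grid_n)))
  meets <- function(v) if (criterion == "alc") v <= l else v >= coverage
  ns <- integer(0); vals <- numeric(0)
  n_opt <- NA_integer_
  expanded <- FALSE
  scan <- function(from, to) {
    for (n in from:to) {
      v <- value_at(n)
      ns <<- c(ns, n); vals <<- c(vals, v)
      if (meets(v)) return(n)
    }
    NA_integer_
  }
  if (bounds[2] >= bounds[1])
    n_opt <- scan(bounds[1], bounds[2])
  if (is.na(n_opt) && expand) {
    expanded <- TRUE
    n_opt <- scan(bounds[2] + 1L, 2L * bounds[2])
  }
  if (is.na(n_opt))
    stop(sprintf(
      "criterion '%s' not met up to n = %d%s", criterion,
      if (expanded) 2L * bounds[2] else bounds[2],
      if (expanded) " (after doubling the search bound)" else ""),
      call. = FALSE)
  res <- list(n_opt = n_opt, criterion = criterion,
              value = vals[length(vals)],
              curve = data.frame(n = ns, value = vals),
              l = l, coverage = coverage, placement = placement,
              woc_space = woc_space, prior = prior,
              frequentist_n = n_hat, bounds = bounds,
              expanded = expanded, seed = as.integer(seed))
  if (criterion == "woc") {
    wc <- worst_coverage(prior, n_opt, l, coverage, placement, woc_space,
                         cd, seed, draws, grid_n)
    res$x_star <- attr(wc, "x_star_set")
    res$c <- attr(wc, "c"); res$d <- attr(wc, "d")
  }
  class(res) <- "ssd"
  res
}

#' @export
print.ssd <- function(x, ...) {
  lab <- c(acc = "average coverage", alc = "average length",
           woc = "worst-outcome coverage")[[x$criterion]]
  cat(sprintf("Bayesian sample size (%s criterion)\n", toupper(x$criterion)))
  cat(sprintf("  n = %d  (%s %.4f; target %s %.3g)\n", x$n_opt, lab, x$value,
              if (x$criterion == "alc") "<=" else ">=",
              if (x$criterion == "alc") x$l else x$coverage))
  cat(sprintf("  searched n in [%d, %d]%s around frequentist benchmark %d\n",
              x$bounds[1], x$bounds[2],
              if (x$expanded) " (expanded)" else "", x$frequentist_n))
  if (!is.null(x$x_star))
    cat("  worst-outcome subset:", paste(x$x_star, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ssd <- function(object, ...) {
  print(object)
  cat("\nDesign: l =", object$l, ", coverage =", object$coverage,
      ", placement =", object$placement, "\n")
  cat("Criterion curve (last rows):\n")
  print(utils::tail(object$curve, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.ssd <- function(object, ...) c(n = object$n_opt)

#' @export
plot.ssd <- function(x, ...) {
  ylab <- c(acc = "average coverage", alc = "average HPD length",
            woc = "worst-outcome coverage")[[x$criterion]]
  plot(x$curve$n, x$curve$value, type = "b", pch = 16, cex = 0.6,
       xlab = "sample size n", ylab = ylab, ...)
  abline(h = if (x$criterion == "alc") x$l else x$coverage, lty = 2)
  points(x$n_opt, x$value, col = 2, pch = 19)
  invisible(x)
}
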