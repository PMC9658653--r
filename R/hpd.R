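# HPD-type credible intervals --------------------------------------------

cred_interval <- function(lower, length, coverage, is_hpd) {
  structure(list(lower = lower, length = length,
                 coverage = coverage, is_hpd = is_hpd),
            class = "cred_interval")
}

#' @export
print.cred_interval <- function(x, ...) {
  cat(sprintf("[%0.5f, %0.5f]  length %.5f, coverage %.5f%s\n",
              x$lower, x$lower + x$length, x$length, x$coverage,
              if (x$is_hpd) "  (HPD)" else ""))
  invisible(x)
}

# endpoint-density HPD verification: equal interior endpoint densities, or
# boundary anchoring at a monotone tail
verify_hpd <- function(post, lower, len, tol = 1e-6) {
  upper <- lower + len
  if (lower <= tol || upper >= 1 - tol) return(TRUE)
  dl <- post$density(lower); du <- post$density(upper)
  abs(dl - du) <= tol * max(1, dl, du)
}

#' Fixed-length interval of maximal posterior coverage
#'
#' Finds the lower bound in `[0, 1 - l]` maximizing the posterior mass of
#' `[lower, lower + l]`; for a unimodal posterior this is the HPD interval
#' of length `l`.  The optimization works on the posterior CDF only, so
#' densities that diverge at the domain ends are handled.  Ties (flat
#' coverage regions) are broken toward the smallest lower bound.
#'
#' @param post a [posterior()] object.
#' @param l interval length, in `(0, 1]`.
#' @return A `cred_interval` with fields `lower`, `length`, `coverage`,
#'   `is_hpd`.
#' @examples
#' hpd_fixed_length(posterior(beta_prior(1, 1), 75, 20), 0.2)
#' @export
hpd_fixed_length <- function(post, l) {
  stopifnot(inherits(post, "posterior"))
  if (l <= 0 || l > 1) stop("'l' must be in (0, 1]", call. = FALSE)
  check_posterior_unimodal(post)
  if (l >= 1) return(cred_interval(0, 1, 1, TRUE))
  cov_at <- function(lo) post$cdf(lo + l) - post$cdf(lo)
  opt <- optimize(cov_at, c(0, 1 - l), maximum = TRUE, tol = 1e-9)
  cands <- c(0, opt$maximum, 1 - l)
  covs <- vapply(cands, cov_at, 0)
  best <- max(covs)
  lower <- min(cands[covs >= best - 1e-12])  # smallest lower on ties
  cred_interval(lower, l, cov_at(lower), verify_hpd(post, lower, l))
}

#' Minimal-length interval of fixed posterior coverage
#'
#' Finds the shortest interval carrying posterior mass `coverage`; for a
#' unimodal posterior this is the HPD interval at that credibility level.
#' Parameterized by the lower tail mass `t`, the interval is
#' `[Q(t), Q(t + coverage)]` with `Q` the posterior quantile function, and
#' `t` is chosen to minimize the length (boundary-anchored solutions at
#' `t = 0` or `t = 1 - coverage` are allowed).
#'
#' @param post a [posterior()] object.
#' @param coverage credibility level in `(0, 1]`.
#' @return A `cred_interval`.
#' @examples
#' hpd_fixed_coverage(posterior(beta_prior(8, 22), 43, 11), 0.95)
#' @export
hpd_fixed_coverage <- function(post, coverage) {
  stopifnot(inherits(post, "posterior"))
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must be in (0, 1]", call. = FALSE)
  check_posterior_unimodal(post)
  if (coverage >= 1) return(cred_interval(0, 1, 1, TRUE))
  len_at <- function(t) post$quantile(t + coverage) - post$quantile(t)
  opt <- optimize(len_at, c(0, 1 - coverage), tol = 1e-10)
  cands <- c(0, opt$minimum, 1 - coverage)
  lens <- vapply(cands, len_at, 0)
  best <- min(lens)
  t0 <- min(cands[lens <= best + 1e-12])
  lower <- post$quantile(t0)
  cred_interval(lower, len_at(t0), coverage,
                verify_hpd(post, lower, len_at(t0)))
}
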