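# Posterior and preposterior computation ---------------------------------

#' Posterior distribution of a binomial proportion
#'
#' For a Beta prior the posterior is conjugate, `Beta(alpha + x,
#' beta + n - x)`, and all downstream quantities use the exact Beta special
#' functions.  For any other prior the kernel
#' `theta^x (1 - theta)^(n - x) f(theta)` is normalized by adaptive
#' quadrature split at the spline knots (the integrand is piecewise smooth
#' there), and the CDF is tabulated on a fine grid with monotone-spline
#' interpolation.
#'
#' @param prior a prior model.
#' @param n number of trials (non-negative integer).
#' @param x number of successes, `0 <= x <= n`.
#' @param grid_n grid resolution for numeric posteriors.
#' @param method `"auto"` uses the conjugate closed form for Beta priors;
#'   `"numeric"` forces the quadrature path for any prior (useful to check
#'   the numeric machinery against conjugate results).
#' @return An object of class `posterior` (subclass `beta_posterior` or
#'   `grid_posterior`) with fields `density`, `cdf`, `quantile` (functions)
#'   and `normalizer` (the marginal likelihood of `x`).
#' @examples
#' p <- posterior(beta_prior(8, 22), n = 10, x = 3)  # Beta(11, 29)
#' p$quantile(0.5)
#' @export
posterior <- function(prior, n, x, grid_n = 4000L,
                      method = c("auto", "numeric")) {
  method <- match.arg(method)
  if (n < 0 || x < 0 || x > n) stop("need 0 <= x <= n", call. = FALSE)
  if (inherits(prior, "beta_prior") && method == "auto") {
    a <- prior$alpha + x; b <- prior$beta + n - x
    norm <- exp(lchoose(n, x) + lbeta(a, b) - lbeta(prior$alpha, prior$beta))
    return(structure(list(
      prior = prior, n = n, x = x, alpha = a, beta = b,
      density = function(t) dbeta(t, a, b),
      cdf = function(t) pbeta(t, a, b),
      quantile = function(p) qbeta(p, a, b),
      normalizer = norm),
      class = c("beta_posterior", "posterior")))
  }
  kern <- function(t) exp(x * log(t) + (n - x) * log1p(-t))
  dom <- if (inherits(prior, "bspline_prior")) prior$basis$domain else c(0, 1)
  brk <- if (inherits(prior, "bspline_prior"))
    unique(prior$basis$knots) else dom
  integrand <- function(t) {
    k <- numeric(length(t))
    pos <- t > 0 & t < 1
    k[pos] <- kern(t[pos])
    k[t <= 0] <- as.numeric(x == 0)
    k[t >= 1] <- as.numeric(x == n)
    k * dprior(prior, t)
  }
  Z <- sum(vapply(seq_len(length(brk) - 1L), function(i)
    integrate(integrand, brk[i], brk[i + 1L], rel.tol = 1e-10,
              abs.tol = 1e-12)$value, 0))
  if (!is.finite(Z) || Z <= 0)
    stop("posterior normalizer underflow", call. = FALSE)
  th <- sort(unique(c(seq(dom[1], dom[2], length.out = grid_n + 1L), brk)))
  dens <- integrand(th) / Z
  # composite trapezoid on the tabulated density, renormalized
  dth <- diff(th)
  steps <- c(0, cumsum(dth * (dens[-1] + dens[-length(dens)]) / 2))
  cdf_grid <- steps / steps[length(steps)]
  cdf_fun <- splinefun(th, cdf_grid, method = "hyman")
  keep <- c(TRUE, diff(cdf_grid) > 0)
  q_fun <- approxfun(cdf_grid[keep], th[keep], rule = 2)
  structure(list(
    prior = prior, n = n, x = x,
    density = function(t) integrand(t) / Z,
    cdf = function(t) pmin(pmax(cdf_fun(pmin(pmax(t, dom[1]), dom[2])), 0), 1),
    quantile = q_fun,
    grid = th, dens_grid = dens, cdf_grid = cdf_grid,
    normalizer = Z * exp(lchoose(n, x))),
    class = c("grid_posterior", "posterior"))
}

#' @export
print.posterior <- function(x, ...) {
  if (inherits(x, "beta_posterior"))
    cat(sprintf("Beta(%g, %g) posterior (n = %d, x = %d)\n",
                x$alpha, x$beta, x$n, x$x))
  else
    cat(sprintf("Numeric posterior on a %d-point grid (n = %d, x = %d)\n",
                length(x$grid), x$n, x$x))
  invisible(x)
}

#' Preposterior predictive distribution of the data
#'
#' The marginal pmf of the number of successes in a future experiment of
#' size `n` under the prior.  Beta priors use the closed-form Beta-Binomial
#' pmf; other priors integrate the binomial kernel against the prior density
#' by adaptive quadrature and normalize.
#'
#' @param prior a prior model.
#' @param n number of trials.
#' @param method `"auto"` or `"numeric"` (force quadrature; see
#'   [posterior()]).
#' @return An object of class `predictive`: a list with `pmf` (vector over
#'   `x = 0..n`), `n` and `prior`.
#' @examples
#' predictive(beta_prior(1, 1), 5)$pmf  # uniform 1/6
#' @export
predictive <- function(prior, n, method = c("auto", "numeric")) {
  method <- match.arg(method)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  xs <- 0:n
  if (inherits(prior, "beta_prior") && method == "auto") {
    a <- prior$alpha; b <- prior$beta
    pmf <- exp(lchoose(n, xs) + lbeta(a + xs, b + n - xs) - lbeta(a, b))
  } else {
    brk <- if (inherits(prior, "bspline_prior"))
      unique(prior$basis$knots) else c(0, 1)
    pmf <- vapply(xs, function(x) {
      integrand <- function(t)
        dbinom(x, n, t) * dprior(prior, t)
      sum(vapply(seq_len(length(brk) - 1L), function(i)
        integrate(integrand, brk[i], brk[i + 1L], rel.tol = 1e-10,
                  abs.tol = 1e-13)$value, 0))
    }, 0)
  }
  structure(list(pmf = pmf / sum(pmf), n = n, prior = prior),
            class = "predictive")
}

#' @export
print.predictive <- function(x, ...) {
  cat(sprintf("Preposterior predictive pmf over x = 0..%d\n", x$n))
  print(stats::setNames(round(x$pmf, 4), 0:x$n))
  invisible(x)
}

# guard against severely multimodal numeric posteriors, for which a single
# HPD-type interval is not meaningful
check_posterior_unimodal <- function(post) {
  if (inherits(post, "beta_posterior")) return(invisible(TRUE))
  d <- post$dens_grid
  floor_ <- 1e-3 * max(d)
  s <- sign(diff(d))
  s <- s[s != 0]
  n_peaks <- sum(diff(s) < 0) + as.integer(length(s) > 0 && s[1] < 0) +
    as.integer(length(s) > 0 && s[length(s)] > 0)
  if (n_peaks > 1) {
    # ignore spurious wiggles far below the dominant mode
    idx <- which(d > floor_)
    ds <- sign(diff(d[idx]))
    ds <- ds[ds != 0]
    if (sum(diff(ds) < 0) + as.integer(length(ds) > 0 && ds[1] < 0) +
        as.integer(length(ds) > 0 && ds[length(ds)] > 0) > 1)
      stop("posterior density appears severely multimodal; ",
           "HPD-type intervals are not defined for it", call. = FALSE)
  }
  invisible(TRUE)
}
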