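# B-spline CDF machinery ------------------------------------------------
#
# The semiparametric prior represents the CDF as a clamped B-spline of
# degree m: boundary knots at the domain ends with multiplicity m + 1 and
# inner knots at the elicited quantile values.  Coefficients are constrained
# to be non-decreasing with first coefficient 0 and last 1, so the spline is
# a CDF and its derivative a (non-negative) density.

bsp_basis <- function(inner, degree, domain = c(0, 1)) {
  if (degree < 2) stop("'degree' must be at least 2", call. = FALSE)
  inner <- inner[inner > domain[1] & inner < domain[2]]
  inner <- sort(unique(inner))
  knots <- c(rep(domain[1], degree + 1), inner, rep(domain[2], degree + 1))
  list(knots = knots, ord = degree + 1L, K = length(inner) + degree + 1L,
       degree = degree, inner = inner, domain = domain)
}

bsp_design <- function(bas, x, deriv = 0L) {
  x <- pmin(pmax(x, bas$domain[1]), bas$domain[2])
  splines::splineDesign(bas$knots, x, ord = bas$ord,
                        derivs = rep(deriv, length(x)), outer.ok = TRUE)
}

# Gram matrix of the density-scale basis: P[j, k] = int B'_j B'_k dy.
# Gauss-Legendre per knot span is exact for the piecewise-polynomial
# integrand (degree 2 (m - 1) <= 2 m - 2, well under 2 * 8 - 1).
bsp_penalty <- function(bas) {
  brk <- unique(bas$knots)
  gl <- pracma::gaussLegendre(8, 0, 1)
  P <- matrix(0, bas$K, bas$K)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    D <- bsp_design(bas, a + (b - a) * gl$x, deriv = 1L)
    P <- P + crossprod(D, D * ((b - a) * gl$w))
  }
  (P + t(P)) / 2
}

#' Fit a semiparametric B-spline prior to elicited quantiles
#'
#' The prior CDF is a monotone clamped B-spline of degree `degree` with inner
#' knots at the elicited quantile values.  Coefficients minimize
#' \deqn{\sum_i (\alpha_i - F(y_{\alpha_i}))^2 + \phi \int f(y)^2 \, dy}
#' subject to non-decreasing coefficients, `F = 0` at the lower and `F = 1`
#' at the upper domain bound, solved as a quadratic program in the
#' coefficient increments.  The penalty integral is the exact Gram-matrix
#' quadratic form of the density-scale basis.  Large `phi` pulls the prior
#' toward the uniform distribution; small `phi` adheres to the expert
#' quantiles as closely as the monotone spline family allows.
#'
#' @param q an [elicited_quantiles()] object (or an [expert_panel()], whose
#'   quartiles are then used).
#' @param degree spline degree `m` (default 4).
#' @param phi positive balancing factor.
#' @param inner_knots optional inner knot locations; defaults to the
#'   elicited quantile values.
#' @return An object of classes `bspline_prior`, `bin_prior` with fields
#'   `basis`, `coef` (CDF-scale coefficients), `phi`, `fit_error` (the
#'   root-mean-square deviation between levels and fitted CDF values) and
#'   `quantiles`.
#' @examples
#' pr <- bspline_prior(quantile(uti_panel()), degree = 4, phi = 1)
#' integrate(function(t) dprior(pr, t), 0, 1)$value  # 1
#' @export
bspline_prior <- function(q, degree = 4, phi, inner_knots = NULL) {
  if (inherits(q, "expert_panel")) q <- quantile(q)
  stopifnot(inherits(q, "elicited_quantiles"))
  if (phi <= 0) stop("'phi' must be positive", call. = FALSE)
  bas <- bsp_basis(if (is.null(inner_knots)) q$values else inner_knots,
                   degree, q$domain)
  K <- bas$K
  B <- bsp_design(bas, q$values)
  P <- bsp_penalty(bas)
  # increments g >= 0 with sum 1; F_j = sum_{i < j} g_i (F_1 = 0, F_K = 1)
  C <- matrix(0, K, K - 1L)
  for (j in 2:K) C[j, 1:(j - 1L)] <- 1
  Bg <- B %*% C
  H <- crossprod(Bg) + phi * crossprod(C, P %*% C)
  H <- (H + t(H)) / 2 + diag(1e-10, K - 1L)
  d <- -as.vector(crossprod(Bg, q$levels))
  sol <- pracma::quadprog(H, d, Aeq = matrix(1, 1, K - 1L), beq = 1,
                          lb = rep(0, K - 1L))
  g <- sol$xmin
  # tidy tiny negative increments from the active-set solution
  g[g < 0 & g > -1e-10] <- 0
  if (any(g < 0)) stop("quadratic program returned infeasible increments",
                       call. = FALSE)
  g <- g / sum(g)
  coefs <- c(0, cumsum(g))
  fitted <- as.vector(B %*% coefs)
  structure(list(basis = bas, coef = coefs, phi = phi,
                 fit_error = sqrt(mean((q$levels - fitted)^2)),
                 fitted_cdf = fitted, quantiles = q,
                 degree = degree),
            class = c("bspline_prior", "bin_prior"))
}

#' @export
dprior.bspline_prior <- function(prior, theta) {
  out <- numeric(length(theta))
  dom <- prior$basis$domain
  inside <- theta >= dom[1] & theta <= dom[2]
  if (any(inside))
    out[inside] <- as.vector(bsp_design(prior$basis, theta[inside],
                                        deriv = 1L) %*% prior$coef)
  pmax(out, 0)
}

#' @export
pprior.bspline_prior <- function(prior, theta) {
  dom <- prior$basis$domain
  th <- pmin(pmax(theta, dom[1]), dom[2])
  as.vector(bsp_design(prior$basis, th) %*% prior$coef)
}

#' @export
rprior.bspline_prior <- function(prior, k, seed = NULL) {
  with_seed(seed, {
    u <- runif(k)
    qfun_bspline(prior)(u)
  })
}

# inverse CDF by monotone interpolation on a fine grid
qfun_bspline <- function(prior, grid_n = 2048L) {
  dom <- prior$basis$domain
  th <- seq(dom[1], dom[2], length.out = grid_n + 1L)
  Fv <- pprior(prior, th)
  keep <- c(TRUE, diff(Fv) > 0)
  approxfun(Fv[keep], th[keep], rule = 2)
}

prior_moment <- function(prior, fun) {
  brk <- unique(prior$basis$knots)
  tot <- 0
  for (i in seq_len(length(brk) - 1L))
    tot <- tot + integrate(function(t) fun(t) * dprior(prior, t),
                           brk[i], brk[i + 1L], rel.tol = 1e-10)$value
  tot
}

#' @export
prior_mean.bspline_prior <- function(prior) prior_moment(prior, identity)

#' @export
prior_var.bspline_prior <- function(prior) {
  m <- prior_mean(prior)
  prior_moment(prior, function(t) (t - m)^2)
}

#' @export
is_unimodal.bspline_prior <- function(prior) {
  # variation-diminishing bound: modes of the density never exceed the sign
  # changes in the first differences of its B-spline coefficients
  bas <- prior$basis
  kn <- bas$knots
  j <- seq_len(bas$K - 1L)
  span <- kn[j + bas$degree + 1L] - kn[j + 1L]  # t_{j+m+1} - t_{j+1}
  dens_coef <- bas$degree * diff(prior$coef) / span
  s <- diff(dens_coef)
  s <- s[abs(s) > 1e-8]
  sum(diff(sign(s)) != 0) <= 1
}

#' @export
print.bspline_prior <- function(x, ...) {
  cat(sprintf(
    "B-spline prior: degree %d, phi %.4g, %d inner knots, fit RMSE %.4f\n",
    x$degree, x$phi, length(x$basis$inner), x$fit_error))
  cat(sprintf("  mean %.4f, ESS %.3g, unimodal: %s\n",
              prior_mean(x), ess(x), is_unimodal(x)))
  invisible(x)
}

#' Calibrate the balancing factor from a target elicitation error
#'
#' Solves `Delta(phi) = delta` for the balancing factor, where `Delta(phi)`
#' is the root-mean-square deviation between the quantile levels and the
#' fitted CDF at the elicited values.  `Delta(phi)` is non-decreasing in
#' `phi`, rising from the constrained least-squares floor (as `phi` tends to
#' 0) to the error of the uniform CDF (as `phi` tends to infinity); the
#' equation is solved by bisection on `log(phi)` over `[1e-4, 1e4]` to a
#' relative tolerance of `1e-4`, breaking ties toward smaller `phi`.
#'
#' @param q an [elicited_quantiles()] object.
#' @param delta target error, e.g. [delta_star()] of the same quantiles.
#' @param degree spline degree.
#' @param interval search interval for `phi`.
#' @return A list with `phi`, the `achieved` error, the `attainable`
#'   range `c(min, max)` of errors, and the fitted `prior`.  If `delta` is
#'   below the attainable minimum the lower search bound is returned with a
#'   warning reporting that minimum.
#' @examples
#' q <- quantile(uti_panel())
#' phi_from_delta(q, delta_star(q))$phi  # about 0.15
#' @export
phi_from_delta <- function(q, delta, degree = 4, interval = c(1e-4, 1e4)) {
  stopifnot(inherits(q, "elicited_quantiles"))
  err <- function(phi) bspline_prior(q, degree, phi)$fit_error
  lo <- log(interval[1]); hi <- log(interval[2])
  e_lo <- err(exp(lo)); e_hi <- err(exp(hi))
  if (delta <= e_lo) {
    if (delta < e_lo - 1e-9)
      warning(sprintf(
        "target delta %.4g below attainable minimum %.4g; returning lower bound",
        delta, e_lo), call. = FALSE)
    phi <- exp(lo)
  } else if (delta >= e_hi) {
    phi <- exp(hi)
  } else {
    while (hi - lo > 1e-4 * max(1, abs(lo))) {
      mid <- (lo + hi) / 2
      if (err(exp(mid)) >= delta) hi <- mid else lo <- mid
    }
    phi <- exp(lo)  # ties toward smaller phi
  }
  fit <- bspline_prior(q, degree, phi)
  list(phi = phi, achieved = fit$fit_error, attainable = c(e_lo, e_hi),
       prior = fit)
}

#' Serialize a fitted prior to a JSON-ready list
#'
#' @param prior a `beta_prior` or `bspline_prior`.
#' @return A plain list that reconstructs the prior exactly via
#'   [prior_from_list()].
#' @export
prior_to_list <- function(prior) {
  if (inherits(prior, "beta_prior"))
    return(list(family = "beta", alpha = prior$alpha, beta = prior$beta))
  list(family = "bspline", degree = prior$degree, phi = prior$phi,
       knots = prior$basis$knots, coef = prior$coef,
       domain = prior$basis$domain,
       levels = prior$quantiles$levels, values = prior$quantiles$values)
}

#' @rdname prior_to_list
#' @param x a list produced by [prior_to_list()] (possibly round-tripped
#'   through JSON).
#' @export
prior_from_list <- function(x) {
  if (identical(x$family, "beta")) return(beta_prior(x$alpha, x$beta))
  if (identical(x$family, "uniform")) return(beta_prior(1, 1))
  q <- elicited_quantiles(x$levels, x$values, x$domain)
  pr <- bspline_prior(q, x$degree, x$phi)
  pr$coef <- x$coef  # exact reload of the stored coefficients
  pr$fitted_cdf <- as.vector(bsp_design(pr$basis, q$values) %*% pr$coef)
  pr$fit_error <- sqrt(mean((q$levels - pr$fitted_cdf)^2))
  pr
}
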