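#' Prior model generics
#'
#' All prior models in the package (Beta and B-spline) share a small
#' contract: a density, a distribution function, moments, random sampling, an
#' effective sample size, and a unimodality flag.
#'
#' @param prior a prior model (`beta_prior` or `bspline_prior`).
#' @param theta numeric vector of proportions.
#' @param k number of draws.
#' @param seed optional integer seed for reproducible draws.
#' @name prior-contract
NULL

#' @rdname prior-contract
#' @export
dprior <- function(prior, theta) UseMethod("dprior")

#' @rdname prior-contract
#' @export
pprior <- function(prior, theta) UseMethod("pprior")

#' @rdname prior-contract
#' @export
rprior <- function(prior, k, seed = NULL) UseMethod("rprior")

#' @rdname prior-contract
#' @export
prior_mean <- function(prior) UseMethod("prior_mean")

#' @rdname prior-contract
#' @export
prior_var <- function(prior) UseMethod("prior_var")

#' @rdname prior-contract
#' @export
is_unimodal <- function(prior) UseMethod("is_unimodal")

#' Prior effective sample size
#'
#' The number of hypothetical patients a prior is worth.  For a Beta(a, b)
#' prior this is a + b.  For any other prior the ESS is that of the Beta
#' distribution obtained by matching the prior's mean and variance.
#'
#' @param prior a prior model.
#' @return A scalar, in patients.
#' @examples
#' ess(beta_prior(8, 22))  # 30
#' @export
ess <- function(prior) UseMethod("ess")

#' @export
ess.default <- function(prior) {
  m <- prior_mean(prior); v <- prior_var(prior)
  if (v >= m * (1 - m))
    stop("variance too large for Beta moment matching; ESS undefined",
         call. = FALSE)
  m * (1 - m) / v - 1
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Beta prior for a binomial proportion
#'
#' @param alpha,beta positive shape parameters.
#' @param provenance optional list recording how the prior was built
#'   (pooled moments, undiscounted shapes, discount factor).
#' @return An object of classes `beta_prior`, `bin_prior`.
#' @examples
#' p <- beta_prior(8, 22)
#' prior_mean(p); ess(p)
#' @export
beta_prior <- function(alpha, beta, provenance = NULL) {
  if (alpha <= 0 || beta <= 0) stop("shapes must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, provenance = provenance),
            class = c("beta_prior", "bin_prior"))
}

#' @export
dprior.beta_prior <- function(prior, theta) dbeta(theta, prior$alpha, prior$beta)

#' @export
pprior.beta_prior <- function(prior, theta) pbeta(theta, prior$alpha, prior$beta)

#' @export
rprior.beta_prior <- function(prior, k, seed = NULL)
  with_seed(seed, rbeta(k, prior$alpha, prior$beta))

#' @export
prior_mean.beta_prior <- function(prior) prior$alpha / (prior$alpha + prior$beta)

#' @export
prior_var.beta_prior <- function(prior) {
  a <- prior$alpha; b <- prior$beta
  a * b / ((a + b)^2 * (a + b + 1))
}

#' @export
is_unimodal.beta_prior <- function(prior)
  prior$alpha >= 1 && prior$beta >= 1

#' @export
ess.beta_prior <- function(prior) prior$alpha + prior$beta

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior  (mean %.4f, ESS %.3g)\n",
              x$alpha, x$beta, prior_mean(x), ess(x)))
  if (!is.null(x$provenance) && !is.null(x$provenance$d0))
    cat(sprintf("  power prior: alpha0 %.4g, beta0 %.4g, d0 %g (%g%% discount)\n",
                x$provenance$alpha0, x$provenance$beta0, x$provenance$d0,
                (1 - x$provenance$d0) * 100))
  invisible(x)
}

#' @export
plot.bin_prior <- function(x, n = 401, ...) {
  th <- seq(0, 1, length.out = n)
  plot(th, dprior(x, th), type = "l", xlab = expression(theta),
       ylab = "prior density", ...)
  invisible(x)
}

#' Beta shapes from pooled moments
#'
#' Inverse moment formulas for the Beta distribution:
#' `alpha0 = mu * (mu (1 - mu) / sigma^2 - 1)` and
#' `beta0 = alpha0 * (1 / mu - 1)`.  Requires `sigma^2 < mu (1 - mu)`.
#'
#' @param mean pooled mean in (0, 1) (or a [pool_opinions()] summary).
#' @param variance pooled variance.
#' @return Named numeric vector `c(alpha0, beta0)`.
#' @examples
#' beta_moments(0.26, 0.00625)  # about (7.74, 22.04)
#' @export
beta_moments <- function(mean, variance) {
  if (inherits(mean, "panel_summary")) {
    variance <- mean$variance; mean <- mean$mean
  }
  if (mean <= 0 || mean >= 1) stop("'mean' must be in (0, 1)", call. = FALSE)
  if (variance <= 0 || variance >= mean * (1 - mean))
    stop("moment matching requires 0 < variance < mean * (1 - mean)",
         call. = FALSE)
  a0 <- mean * (mean * (1 - mean) / variance - 1)
  c(alpha0 = a0, beta0 = a0 * (1 / mean - 1))
}

#' Discount Beta shapes through a power prior
#'
#' The elicited information enters the prior raised to the power `d0`:
#' the prior is `Beta(alpha0 * d0 + 1, beta0 * d0 + 1)`.  `d0 = 0` discards
#' the expert information entirely (uniform Beta(1, 1)); `d0 = 1` keeps it
#' all.  The discounting percentage is `(1 - d0) * 100`.
#'
#' @param alpha0,beta0 undiscounted Beta shapes (e.g. from [beta_moments()]).
#' @param d0 weight of the expert information, in `[0, 1]`.
#' @return A [beta_prior()] carrying its provenance.
#' @examples
#' discount_beta(7, 21, 0.5)  # Beta(4.5, 11.5)
#' @export
discount_beta <- function(alpha0, beta0, d0) {
  if (d0 < 0 || d0 > 1) stop("'d0' must be in [0, 1]", call. = FALSE)
  beta_prior(alpha0 * d0 + 1, beta0 * d0 + 1,
             provenance = list(alpha0 = alpha0, beta0 = beta0, d0 = d0))
}

#' Elicit a power-prior Beta distribution from an expert panel
#'
#' Pools the panel, moment-matches Beta shapes, and applies power-prior
#' discounting.  With `round_prior = TRUE` the fully informative (`d0 = 1`)
#' prior is rounded to integer shapes and the undiscounted shapes are derived
#' from it, which turns the pooled moments (0.2625, 0.00625) into the
#' conventional Beta(8, 22) / Beta(4.5, 11.5) / Beta(1, 1) family.
#'
#' @param panel an [expert_panel()].
#' @param d0 power-prior weight in `[0, 1]`.
#' @param round_prior round the informative prior to integer shapes.
#' @return A [beta_prior()].
#' @examples
#' elicit_beta_prior(uti_panel(), d0 = 1, round_prior = TRUE)  # Beta(8, 22)
#' @export
elicit_beta_prior <- function(panel, d0 = 1, round_prior = FALSE) {
  s <- pool_opinions(panel)
  ab <- beta_moments(s)
  a0 <- ab[["alpha0"]]; b0 <- ab[["beta0"]]
  if (round_prior) {
    # the moment-matched Beta itself is rounded to integer shapes and the
    # undiscounted shapes back-derived, so d0 = 1 yields exactly that Beta
    a0 <- round(a0) - 1
    b0 <- round(b0) - 1
  }
  pr <- discount_beta(a0, b0, d0)
  pr$provenance$mean <- s$mean
  pr$provenance$variance <- s$variance
  pr$provenance$rounded <- round_prior
  pr
}
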