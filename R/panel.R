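#' Create an expert panel of point opinions
#'
#' An expert panel holds the raw point guesses of several experts about a
#' probability (for example, the probability of an adverse event).  Opinions
#' must lie strictly inside (0, 1) and at least two experts are required so
#' that a variance can be computed.
#'
#' @param opinions numeric vector of probabilities strictly in (0, 1), one per
#'   expert.
#' @param label optional free-text description of the panel.
#' @return An object of class `expert_panel`.
#' @examples
#' uti_panel()
#' expert_panel(c(0.1, 0.2, 0.3), label = "toy")
#' @seealso [pool_opinions()], [quantile.expert_panel()], [generate_panel()]
#' @export
expert_panel <- function(opinions, label = NULL) {
  opinions <- as.numeric(opinions)
  if (length(opinions) < 2L)
    stop("an expert panel needs at least 2 opinions", call. = FALSE)
  if (anyNA(opinions) || any(opinions <= 0) || any(opinions >= 1))
    stop("all opinions must be strictly between 0 and 1", call. = FALSE)
  structure(list(opinions = opinions, label = label), class = "expert_panel")
}

#' The built-in pediatric UTI expert panel
#'
#' The eight expert guesses of the probability of a renal scar event used as
#' the package's worked example: a panel of clinicians asked for the chance
#' that an infant with a first febrile urinary tract infection shows renal
#' scarring six months after the acute episode.
#'
#' @return An [expert_panel()] with eight opinions.
#' @export
uti_panel <- function() {
  expert_panel(c(0.30, 0.25, 0.15, 0.40, 0.30, 0.20, 0.20, 0.30),
               label = "pediatric UTI renal scar panel (8 experts)")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat("Expert panel", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  opinions:", paste(format(x$opinions), collapse = ", "), "\n")
  s <- pool_opinions(x)
  cat(sprintf("  pooled mean %.4f, variance %.5g (n = %d)\n",
              s$mean, s$variance, s$n_experts))
  invisible(x)
}

#' Pool expert opinions into summary moments
#'
#' Combines point guesses by their arithmetic mean and sample variance
#' (denominator n - 1).  These moments feed the Beta moment-matching step of
#' [elicit_beta_prior()].
#'
#' @param panel an [expert_panel()].
#' @return An object of class `panel_summary`: a list with elements `mean`,
#'   `variance` and `n_experts`.
#' @examples
#' pool_opinions(uti_panel())  # mean 0.2625, variance 0.00625
#' @export
pool_opinions <- function(panel) {
  stopifnot(inherits(panel, "expert_panel"))
  y <- panel$opinions
  structure(list(mean = mean(y), variance = var(y), n_experts = length(y)),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Pooled panel summary: mean %.4f, variance %.5g, %d experts\n",
              x$mean, x$variance, x$n_experts))
  invisible(x)
}

#' @export
summary.expert_panel <- function(object, ...) pool_opinions(object)

#' Elicited quantiles of an expert panel
#'
#' Empirical quantiles of the expert opinions under the linear-interpolation
#' convention between order statistics (index `h = (n - 1) * level`, R's
#' default type-7 rule).  The default levels are the three quartiles, the most
#' common fractiles used in expert elicitation.
#'
#' @param x an [expert_panel()].
#' @param probs quantile levels, strictly increasing within (0, 1).
#' @param domain lower/upper bounds of the parameter space the probabilities
#'   live in; used later for normalization in [delta_star()].
#' @param ... unused.
#' @return An [elicited_quantiles()] object.
#' @examples
#' quantile(uti_panel())  # 0.2, 0.275, 0.3
#' @export
quantile.expert_panel <- function(x, probs = c(0.25, 0.5, 0.75),
                                  domain = c(0, 1), ...) {
  vals <- unname(quantile(x$opinions, probs = probs, type = 7))
  elicited_quantiles(levels = probs, values = vals, domain = domain)
}

#' Construct a set of elicited quantiles
#'
#' @param levels quantile levels (probabilities), strictly increasing in
#'   (0, 1).
#' @param values elicited quantile values; non-decreasing, inside `domain`.
#' @param domain numeric length-2 vector, the bounds of the parameter space.
#' @return An object of class `elicited_quantiles` with fields `levels`,
#'   `values`, `domain`, `p`.
#' @export
elicited_quantiles <- function(levels, values, domain = c(0, 1)) {
  levels <- as.numeric(levels); values <- as.numeric(values)
  if (length(levels) == 0L || length(levels) != length(values))
    stop("'levels' and 'values' must be non-empty and of equal length",
         call. = FALSE)
  if (any(diff(levels) <= 0) || any(levels <= 0) || any(levels >= 1))
    stop("'levels' must be strictly increasing within (0, 1)", call. = FALSE)
  if (any(diff(values) < 0))
    stop("'values' must be non-decreasing", call. = FALSE)
  if (any(values < domain[1]) || any(values > domain[2]))
    stop("'values' must lie inside 'domain'", call. = FALSE)
  structure(list(levels = levels, values = values,
                 domain = as.numeric(domain), p = length(levels)),
            class = "elicited_quantiles")
}

#' @export
print.elicited_quantiles <- function(x, ...) {
  cat("Elicited quantiles on domain [",
      x$domain[1], ", ", x$domain[2], "]\n", sep = "")
  print(stats::setNames(x$values, format(x$levels)))
  invisible(x)
}

#' Data-driven elicitation error
#'
#' The default expected elicitation error used to calibrate the B-spline
#' balancing factor.  Quantile values are first normalized to the unit
#' interval with respect to the domain bounds; the error is then half the
#' root-mean-square deviation between the normalized values and their levels.
#' The alternative `method = "quadratic"` returns half the mean squared
#' deviation (the plain quadratic loss, without the square root).
#'
#' @param q an [elicited_quantiles()] object.
#' @param method `"half-rmse"` (default) or `"quadratic"`.
#' @return The scalar error.
#' @examples
#' delta_star(quantile(uti_panel()))  # about 0.146
#' @export
delta_star <- function(q, method = c("half-rmse", "quadratic")) {
  stopifnot(inherits(q, "elicited_quantiles"))
  method <- match.arg(method)
  j <- q$domain[1]; k <- q$domain[2]
  if (k <= j) stop("degenerate domain: upper bound must exceed lower bound",
                   call. = FALSE)
  ystar <- (q$values - j) / (k - j)
  msq <- mean((ystar - q$levels)^2)
  if (method == "half-rmse") sqrt(msq) / 2 else msq / 2
}

#' Read expert opinions from CSV or JSON
#'
#' CSV files must have a column `opinion` (an optional `expert_id` column is
#' ignored); JSON files must contain a plain array of numbers.
#'
#' @param path path to a `.csv` or `.json` file.
#' @param label optional panel label; defaults to the file name.
#' @return An [expert_panel()].
#' @export
read_opinions <- function(path, label = basename(path)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    y <- jsonlite::fromJSON(path)
    if (!is.numeric(y)) stop("JSON opinions file must be a numeric array",
                             call. = FALSE)
  } else {
    d <- read.csv(path)
    if (!"opinion" %in% names(d))
      stop("CSV opinions file must have an 'opinion' column", call. = FALSE)
    y <- d$opinion
  }
  expert_panel(y, label = label)
}

#' Generate a synthetic expert panel
#'
#' Draws expert point guesses from a Beta distribution with the requested
#' mean and spread, then rounds them to a grid emulating the resolution at
#' which experts typically state probabilities (multiples of 0.05 by
#' default), and clips them inside (0, 1).
#'
#' @param n_experts number of experts (at least 2).
#' @param true_mean centre of the generating Beta distribution, in (0, 1).
#' @param spread standard deviation of the generating Beta distribution; must
#'   satisfy `spread^2 < true_mean * (1 - true_mean)`.
#' @param grid rounding grid for the stated opinions.
#' @param seed integer seed; the same seed always returns the same panel.
#' @return An [expert_panel()].
#' @examples
#' generate_panel(8, 0.26, 0.08, seed = 1)
#' @export
generate_panel <- function(n_experts, true_mean, spread = 0.08, grid = 0.05,
                           seed = 1L) {
  if (n_experts < 2L) stop("need at least 2 experts", call. = FALSE)
  if (true_mean <= 0 || true_mean >= 1)
    stop("'true_mean' must be in (0, 1)", call. = FALSE)
  v <- spread^2
  if (v >= true_mean * (1 - true_mean))
    stop("'spread' is incompatible with 'true_mean' for a Beta distribution",
         call. = FALSE)
  ab <- beta_moments(true_mean, v)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  y <- rbeta(n_experts, ab[1], ab[2])
  y <- round(y / grid) * grid
  y <- pmin(pmax(y, grid), 1 - grid)
  expert_panel(y, label = sprintf("synthetic panel (mean %.2f, seed %d)",
                                  true_mean, as.integer(seed)))
}
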