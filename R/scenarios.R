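# Scenario presets and the end-to-end pipeline ---------------------------

#' Build the preset prior scenarios from an expert panel
#'
#' Six standard scenarios: Beta power priors at `d0 = 1` (informative),
#' `d0 = 0.5` (low-informative) and `d0 = 0` (uninformative), and B-spline
#' priors at `phi` calibrated from the data-driven elicitation error
#' (informative), `phi = 1` (low-informative) and `phi = 45`
#' (uninformative).
#'
#' @param panel an [expert_panel()].
#' @param scenarios subset of the preset names to build.
#' @param round_prior round the Beta priors to integer shapes (see
#'   [elicit_beta_prior()]).
#' @param degree B-spline degree.
#' @return Named list of prior models.
#' @examples
#' names(scenario_priors(uti_panel()))
#' @export
scenario_priors <- function(panel,
                            scenarios = c("beta-informative",
                                          "beta-low-informative",
                                          "beta-uninformative",
                                          "bspline-informative",
                                          "bspline-low-informative",
                                          "bspline-uninformative"),
                            round_prior = TRUE, degree = 4) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  q <- quantile(panel)
  out <- list()
  for (sc in scenarios) {
    out[[sc]] <- switch(sc,
      "beta-informative" = elicit_beta_prior(panel, 1, round_prior),
      "beta-low-informative" = elicit_beta_prior(panel, 0.5, round_prior),
      "beta-uninformative" = elicit_beta_prior(panel, 0, round_prior),
      "bspline-informative" =
        phi_from_delta(q, delta_star(q), degree)$prior,
      "bspline-low-informative" = bspline_prior(q, degree, phi = 1),
      "bspline-uninformative" = bspline_prior(q, degree, phi = 45))
  }
  out
}

#' Run all criteria across prior scenarios
#'
#' The package's end-to-end design table: for each preset prior scenario and
#' each requested criterion, the optimal Bayesian sample size, searched in a
#' common window around the frequentist precision benchmark computed from
#' the pooled (unrounded) panel mean.
#'
#' @inheritParams scenario_priors
#' @inheritParams design-diagnostics
#' @param criteria subset of `c("acc", "alc", "woc")`.
#' @param keep_curves retain each cell's per-`n` criterion curve.
#' @return An object of class `ssd_report`.
#' @examples
#' \donttest{
#' rep <- ssd_scenarios(uti_panel(), scenarios = "beta-informative")
#' print(rep)
#' }
#' @export
ssd_scenarios <- function(panel, criteria = c("acc", "alc", "woc"),
                          scenarios = c("beta-informative",
                                        "beta-low-informative",
                                        "beta-uninformative",
                                        "bspline-informative",
                                        "bspline-low-informative",
                                        "bspline-uninformative"),
                          l = 0.2, coverage = 0.95,
                          placement = "hpd", woc_space = "formula",
                          round_prior = TRUE, degree = 4, seed = 1L,
                          grid_n = 4000L, keep_curves = FALSE) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  s <- pool_opinions(panel)
  n_hat <- frequentist_n(s$mean, l, coverage)
  bounds <- search_bounds(n_hat)
  priors <- scenario_priors(panel, scenarios, round_prior, degree)
  cells <- expand.grid(scenario = names(priors), criterion = criteria,
                       stringsAsFactors = FALSE)
  cells$n_opt <- NA_integer_
  cells$value <- NA_real_
  cells$failed <- FALSE
  curves <- list()
  for (i in seq_len(nrow(cells))) {
    fit <- tryCatch(
      sample_size(priors[[cells$scenario[i]]], cells$criterion[i],
                  l = l, coverage = coverage, placement = placement,
                  woc_space = woc_space, n_range = bounds, seed = seed,
                  grid_n = grid_n),
      error = function(e) e)
    if (inherits(fit, "error")) {
      cells$failed[i] <- TRUE
      curves[[paste(cells$scenario[i], cells$criterion[i], sep = ".")]] <-
        conditionMessage(fit)
    } else {
      cells$n_opt[i] <- fit$n_opt
      cells$value[i] <- fit$value
      if (keep_curves)
        curves[[paste(cells$scenario[i], cells$criterion[i], sep = ".")]] <-
          fit$curve
    }
  }
  prior_info <- lapply(priors, function(p) {
    info <- list(ess = tryCatch(ess(p), error = function(e) NA_real_),
                 mean = prior_mean(p))
    lst <- prior_to_list(p)
    lst$knots <- lst$coef <- lst$levels <- lst$values <- lst$domain <- NULL
    c(info, lst)
  })
  structure(list(
    panel = list(opinions = panel$opinions, label = panel$label,
                 mean = s$mean, variance = s$variance,
                 n_experts = s$n_experts),
    design = list(l = l, coverage = coverage, placement = placement,
                  woc_space = woc_space, round_prior = round_prior,
                  degree = degree, seed = as.integer(seed)),
    frequentist_n = n_hat, bounds = bounds,
    priors = prior_info, cells = cells, curves = curves),
    class = "ssd_report")
}

#' @export
print.ssd_report <- function(x, ...) {
  cat("Bayesian sample size report\n")
  cat(sprintf("  panel: %d experts, mean %.4f, variance %.5g\n",
              x$panel$n_experts, x$panel$mean, x$panel$variance))
  cat(sprintf("  design: l = %g, coverage = %g; frequentist benchmark %d, search [%d, %d]\n",
              x$design$l, x$design$coverage, x$frequentist_n,
              x$bounds[1], x$bounds[2]))
  tab <- stats::reshape(x$cells[, c("scenario", "criterion", "n_opt")],
                        idvar = "scenario", timevar = "criterion",
                        direction = "wide")
  names(tab) <- sub("^n_opt\\.", "", names(tab))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a scenario report to JSON and/or CSV
#'
#' @param report an `ssd_report`.
#' @param json,csv output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_report <- function(report, json = NULL, csv = NULL) {
  stopifnot(inherits(report, "ssd_report"))
  if (!is.null(json)) {
    payload <- list(schema_version = "1.0",
                    panel = report$panel, design = report$design,
                    frequentist_n = report$frequentist_n,
                    bounds = report$bounds,
                    priors = report$priors,
                    cells = report$cells)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv))
    write.csv(report$cells, csv, row.names = FALSE)
  invisible(report)
}

#' Structural validation of a report JSON file
#'
#' Checks a written report against the schema shipped in
#' `inst/schema/report-schema.json`: required top-level fields, required
#' cell columns, and field types.
#'
#' @param path path to a JSON report written by [write_report()].
#' @return `TRUE` (invisibly) if valid, otherwise an error.
#' @export
validate_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  schema <- jsonlite::fromJSON(system.file("schema", "report-schema.json",
                                           package = "bssd"))
  req <- schema$required
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("report is missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cell_req <- schema$properties$cells$items$required
  missing_c <- setdiff(cell_req, names(x$cells))
  if (length(missing_c))
    stop("report cells are missing columns: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  if (!is.numeric(x$frequentist_n))
    stop("'frequentist_n' must be numeric", call. = FALSE)
  invisible(TRUE)
}

#' Run the pipeline from a configuration
#'
#' Ties the stages together: read or accept an expert panel (or an explicit
#' prior), build the requested scenario priors, run the requested criteria,
#' and write JSON/CSV reports.  The configuration is a named list, or a path
#' to a YAML/JSON file with the same fields: `opinions` (path or numeric
#' vector) or `prior` (a list as produced by [prior_to_list()]), exactly one
#' of the two; `scenarios`, `criteria`, `design` (`l`, `coverage`,
#' `placement`, `woc_space`, `round_prior`, `degree`), `seed`, and `output`
#' (`json`, `csv`).
#'
#' @param config named list or path to a YAML/JSON configuration file.
#' @return The `ssd_report` (or a single-cell report when an explicit prior
#'   is supplied), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configurations",
             call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config)
  }
  has_op <- !is.null(config$opinions); has_pr <- !is.null(config$prior)
  if (has_op == has_pr)
    stop("supply exactly one of 'opinions' or 'prior'", call. = FALSE)
  design <- modifyList(list(l = 0.2, coverage = 0.95, placement = "hpd",
                            woc_space = "formula", round_prior = TRUE,
                            degree = 4),
                       if (is.null(config$design)) list() else config$design)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  criteria <- if (is.null(config$criteria)) c("acc", "alc", "woc")
              else config$criteria
  if (has_op) {
    panel <- if (is.character(config$opinions)) read_opinions(config$opinions)
             else expert_panel(config$opinions)
    scenarios <- if (is.null(config$scenarios))
      eval(formals(ssd_scenarios)$scenarios) else config$scenarios
    report <- ssd_scenarios(panel, criteria = criteria,
                            scenarios = scenarios,
                            l = design$l, coverage = design$coverage,
                            placement = design$placement,
                            woc_space = design$woc_space,
                            round_prior = design$round_prior,
                            degree = design$degree, seed = seed)
  } else {
    if (!is.null(config$scenarios))
      stop("scenario presets are only valid with 'opinions'", call. = FALSE)
    prior <- prior_from_list(config$prior)
    cells <- data.frame(scenario = "explicit-prior", criterion = criteria,
                        n_opt = NA_integer_, value = NA_real_,
                        failed = FALSE)
    for (i in seq_len(nrow(cells))) {
      fit <- tryCatch(
        sample_size(prior, cells$criterion[i], l = design$l,
                    coverage = design$coverage,
                    placement = design$placement,
                    woc_space = design$woc_space, seed = seed),
        error = function(e) e)
      if (inherits(fit, "error")) cells$failed[i] <- TRUE
      else { cells$n_opt[i] <- fit$n_opt; cells$value[i] <- fit$value }
    }
    report <- structure(list(
      panel = NULL,
      design = c(design, list(seed = seed)),
      frequentist_n = frequentist_n(prior_mean(prior), design$l,
                                    design$coverage),
      bounds = search_bounds(frequentist_n(prior_mean(prior), design$l,
                                           design$coverage)),
      priors = list("explicit-prior" = prior_to_list(prior)),
      cells = cells, curves = list()), class = "ssd_report")
  }
  if (!is.null(config$output))
    write_report(report, json = config$output$json, csv = config$output$csv)
  invisible(report)
}
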