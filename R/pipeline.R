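#' Analysis configuration
#'
#' Bundles every input and setting of the full analysis. Data can come from
#' the four CSV inputs or from a synthetic-generator block; exactly one of
#' the two must be supplied.
#'
#' @param panel,moderators,projections,groups paths to the four CSV inputs
#'   (see the `read_*` functions), or NULL when `synthetic` is given.
#' @param synthetic optional [generator_config()] used to generate the data
#'   in memory.
#' @param strata strata to analyse (each is fitted as a separate model).
#' @param priors [prior_config()].
#' @param mcmc [mcmc_config()].
#' @param selection_threshold correlation-screen threshold.
#' @param scenarios scenario table (see [default_scenarios()]); NULL skips
#'   forecasting.
#' @param n_forecast_draws elasticity draws per country for forecasts.
#' @param out_dir output directory; NULL keeps results in memory only.
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(panel = NULL, moderators = NULL,
                            projections = NULL, groups = NULL,
                            synthetic = NULL,
                            strata = "overall",
                            priors = prior_config(), mcmc = mcmc_config(),
                            selection_threshold = 0.7,
                            scenarios = default_scenarios(),
                            n_forecast_draws = 1000,
                            out_dir = NULL, seed = 1L) {
  if (is.null(synthetic)) {
    paths <- c(panel = panel, moderators = moderators,
               projections = projections)
    if (any(vapply(list(panel, moderators, projections), is.null, logical(1)))) {
      stop("either a synthetic block or panel/moderators/projections paths ",
           "must be supplied", call. = FALSE)
    }
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths) > 0) {
      stop("input file(s) not found: ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(panel = panel, moderators = moderators,
                 projections = projections, groups = groups,
                 synthetic = synthetic, strata = strata,
                 priors = priors, mcmc = mcmc,
                 selection_threshold = selection_threshold,
                 scenarios = scenarios,
                 n_forecast_draws = n_forecast_draws,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Scalar fields map directly onto [analysis_config()] arguments; the
#' `priors`, `mcmc` and `synthetic` blocks map onto [prior_config()],
#' [mcmc_config()] and [generator_config()].
#'
#' @param path YAML file.
#' @return `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("panel", "moderators", "projections",
                                  "groups", "strata", "selection_threshold",
                                  "n_forecast_draws", "out_dir", "seed"))]
  if (!is.null(y$priors)) args$priors <- do.call(prior_config, y$priors)
  if (!is.null(y$mcmc)) args$mcmc <- do.call(mcmc_config, y$mcmc)
  if (!is.null(y$synthetic)) {
    args$synthetic <- do.call(generator_config, y$synthetic)
  }
  do.call(analysis_config, args)
}

config_hash <- function(config) {
  # hash the scientific configuration only, not where outputs land
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full two-stage analysis
#'
#' Executes, for each configured stratum: the functional-form contest, the
#' fast two-step elasticity estimation (per-country OLS), moderator forward
#' selection, the final Gibbs fit with the selected moderators, Geweke
#' convergence diagnostics on all second-stage coefficient chains (soft
#' failure with a warning when any `|Z| >= 1.96`), posterior summarization,
#' and scenario forecasting. When `out_dir` is set, writes `mape_table.csv`,
#' `selection_trace.csv`, `summary.csv`, `elasticities.csv`, `forecast.csv`
#' and `run_report.json`, each numeric CSV stamped with the configuration
#' hash.
#'
#' @param config [analysis_config()].
#' @return List of class `analysis_report`: per-stratum results plus the
#'   run metadata (config hash, seed, versions, collected warnings).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  hash <- config_hash(config)
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (!is.null(config$synthetic)) {
    mods <- standardize_moderators(
      generate_moderators(config$synthetic, seed = config$seed))
    gen <- generate_panel(config$synthetic, mods, seed = config$seed + 1L)
    panel <- gen$panel
    projections <- generate_projections(config$synthetic,
                                        seed = config$seed + 2L)
    truth <- gen$truth
  } else {
    panel <- read_panel(config$panel)
    mods <- standardize_moderators(read_moderators(config$moderators))
    projections <- read_projections(config$projections)
    truth <- NULL
  }

  timings <- list()
  strata_results <- list()
  for (stratum in config$strata) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers({
      contest <- form_contest(panel, stratum = stratum)
      ols <- ols_elasticities(panel, stratum = stratum)
      sel <- forward_select(setNames(ols$beta, ols$country), mods,
                            threshold = config$selection_threshold,
                            alpha_response = setNames(ols$alpha, ols$country))
      mcmc_s <- config$mcmc
      mcmc_s$seed <- config$seed + 100L * match(stratum, config$strata)
      fit <- run_gibbs(panel, mods, stratum = stratum,
                       selected = sel$selected,
                       priors = config$priors, mcmc = mcmc_s)
      gw <- geweke_table(fit)
      if (any(!gw$converged)) {
        warning("Geweke diagnostic flags non-convergence for: ",
                paste(gw$variable[!gw$converged], collapse = ", "),
                call. = FALSE)
      }
      summ <- summarize_posterior(fit)
      fc <- NULL
      if (!is.null(config$scenarios)) {
        fc <- run_scenarios(panel, mods, projections,
                            scenarios = config$scenarios,
                            stratum = stratum, selected = sel$selected,
                            priors = config$priors, mcmc = mcmc_s,
                            n_draws = config$n_forecast_draws,
                            seed = config$seed + 7L,
                            fits = list(full = fit))
      }
      list(contest = contest, ols = ols, selection = sel, fit = fit,
           geweke = gw, summary = summ, forecast = fc)
    }, warning = note)
    timings[[stratum]] <- proc.time()[["elapsed"]] - t0
    strata_results[[stratum]] <- res
  }

  report <- structure(list(
    strata = strata_results, panel = panel, moderators = mods,
    truth = truth, config = config, config_hash = hash,
    seed = config$seed, warnings = warnings_seen,
    versions = list(obelast = as.character(utils::packageVersion("obelast")),
                    R = R.version.string),
    timings_sec = timings), class = "analysis_report")

  if (!is.null(config$out_dir)) write_analysis_outputs(report)
  report
}

write_analysis_outputs <- function(report) {
  dir.create(report$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(report$config$out_dir, f)
  hash <- report$config_hash
  strata <- names(report$strata)

  per_stratum <- function(extract) {
    do.call(rbind, lapply(strata, function(s) {
      df <- extract(report$strata[[s]])
      if (is.null(df) || nrow(df) == 0) return(NULL)
      cbind(stratum = s, df)
    }))
  }
  write_stamped_csv(per_stratum(function(r) r$contest$mape_table),
                    out("mape_table.csv"), hash)
  write_stamped_csv(per_stratum(function(r) r$selection$trace),
                    out("selection_trace.csv"), hash)
  write_stamped_csv(per_stratum(function(r) r$summary$theta),
                    out("summary.csv"), hash)
  write_stamped_csv(per_stratum(function(r) r$summary$elasticities),
                    out("elasticities.csv"), hash)
  fc <- per_stratum(function(r) {
    if (is.null(r$forecast)) return(NULL)
    do.call(rbind, lapply(names(r$forecast$results), function(sc) {
      fr <- r$forecast$results[[sc]]
      data.frame(scenario = sc, year = fr$years,
                 aggregate_mean = fr$mean, lower95 = fr$lower,
                 upper95 = fr$upper, stringsAsFactors = FALSE)
    }))
  })
  if (!is.null(fc)) write_stamped_csv(fc, out("forecast.csv"), hash)
  jsonlite::write_json(list(
    config_hash = hash, seed = report$seed, versions = report$versions,
    warnings = report$warnings, timings_sec = report$timings_sec),
    out("run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report$config$out_dir)
}
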