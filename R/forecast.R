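#' Linear elasticity-decline ramp
#'
#' Per-year multipliers for a policy scenario in which elasticities decline
#' linearly over the forecast horizon for a total drop of `d` by the final
#' year: `s_y = 1 - d * y / K` for `y = 1..K`.
#'
#' @param d total proportional decline over the horizon (`0 <= d < 1`).
#' @param horizon_years number of horizon years K.
#' @param mode `"ramp"` (gradual, default) or `"step"` (full drop from the
#'   first horizon year).
#' @return Numeric vector of K factors; the final factor is exactly `1 - d`.
#' @export
apply_ramp <- function(d, horizon_years, mode = c("ramp", "step")) {
  mode <- match.arg(mode)
  if (d < 0 || d >= 1) stop("decline d must be in [0, 1)", call. = FALSE)
  if (horizon_years < 1) stop("horizon must have at least 1 year", call. = FALSE)
  if (mode == "step") return(rep(1 - d, horizon_years))
  1 - d * seq_len(horizon_years) / horizon_years
}

#' Project one country's prevalence trajectory under elasticity draws
#'
#' For each elasticity draw b and year y, prevalence compounds as
#' `prev_{y+1} = prev_y * (1 + s_y * beta_b * g_y / 100)`, where `g_y` is the
#' projected annual income growth in percent and `s_y` the scenario's
#' elasticity multiplier (1 in bridge years of actual growth). Trajectories
#' are clamped to [0, 100] with a clamp-event counter (attribute
#' `"n_clamped"`).
#'
#' @param start_prev starting prevalence in percent, inside (0, 100).
#' @param elasticity_draws numeric vector of elasticity draws.
#' @param growth_path data frame with columns `year`, `growth_pct`,
#'   `is_bridge`, ordered by year.
#' @param ramp multipliers for the non-bridge (horizon) years, as from
#'   [apply_ramp()]; default all 1.
#' @return Matrix of dim (draws x years) of prevalence in percent, with the
#'   years as column names.
#' @export
project_country <- function(start_prev, elasticity_draws, growth_path,
                            ramp = NULL) {
  if (start_prev <= 0 || start_prev >= 100) {
    stop("start_prev must be inside (0, 100)", call. = FALSE)
  }
  if (length(elasticity_draws) < 1) stop("need at least one draw", call. = FALSE)
  if (any(growth_path$growth_pct <= -100)) {
    stop("growth at or below -100% is out of domain", call. = FALSE)
  }
  K <- sum(!growth_path$is_bridge)
  if (is.null(ramp)) ramp <- rep(1, K)
  if (length(ramp) != K) {
    stop("ramp length must equal the number of horizon years", call. = FALSE)
  }
  s <- numeric(nrow(growth_path))
  s[growth_path$is_bridge] <- 1
  s[!growth_path$is_bridge] <- ramp
  B <- length(elasticity_draws)
  out <- matrix(NA_real_, B, nrow(growth_path),
                dimnames = list(NULL, growth_path$year))
  prev <- rep(start_prev, B)
  n_clamped <- 0L
  for (y in seq_len(nrow(growth_path))) {
    prev <- prev * (1 + s[y] * elasticity_draws * growth_path$growth_pct[y] / 100)
    hi <- prev > 100
    lo <- prev < 0
    n_clamped <- n_clamped + sum(hi) + sum(lo)
    prev[hi] <- 100
    prev[lo] <- 0
    out[, y] <- prev
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Aggregate per-country trajectories into a cross-country forecast
#'
#' Unweighted cross-country mean within each draw and year, then the
#' posterior mean trajectory and equal-tailed 2.5/97.5-percentile band
#' across draws. Average annual growth over the horizon is reported both as
#' the mean (with prediction interval) of per-draw CAGRs and as the CAGR of
#' the mean trajectory.
#'
#' @param country_trajectories named list of (draws x years) matrices from
#'   [project_country()], all on the same year grid.
#' @param start_prev named vector of starting prevalences (the aggregate
#'   baseline for growth when there are no bridge years).
#' @param is_bridge logical vector flagging bridge years (same year grid).
#' @return Object of class `forecast_result`.
#' @export
aggregate_forecast <- function(country_trajectories, start_prev, is_bridge) {
  grids <- lapply(country_trajectories, colnames)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1) {
    stop("country trajectories are on different year grids", call. = FALSE)
  }
  agg <- Reduce(`+`, country_trajectories) / length(country_trajectories)
  years <- as.integer(colnames(country_trajectories[[1]]))
  mean_traj <- colMeans(agg)
  lower <- apply(agg, 2, quantile, probs = 0.025)
  upper <- apply(agg, 2, quantile, probs = 0.975)

  # growth measured over the horizon years only
  horizon_idx <- which(!is_bridge)
  n_h <- length(horizon_idx)
  base_idx <- if (min(horizon_idx) > 1) min(horizon_idx) - 1L else 0L
  base_draws <- if (base_idx > 0) agg[, base_idx] else
    rep(mean(start_prev), nrow(agg))
  end_draws <- agg[, max(horizon_idx)]
  cagr_draws <- compute_cagr(base_draws, end_draws, n_h)
  growth <- data.frame(
    mean = mean(cagr_draws),
    lower = unname(quantile(cagr_draws, 0.025)),
    upper = unname(quantile(cagr_draws, 0.975)),
    of_mean_trajectory = compute_cagr(
      if (base_idx > 0) mean_traj[base_idx] else mean(start_prev),
      mean_traj[max(horizon_idx)], n_h))
  n_clamped <- sum(vapply(country_trajectories,
                          function(m) attr(m, "n_clamped") %||% 0L,
                          numeric(1)))
  structure(list(years = years, is_bridge = is_bridge,
                 draws = agg, mean = mean_traj, lower = lower, upper = upper,
                 growth = growth, n_clamped = n_clamped),
            class = "forecast_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The five standard sensitivity scenarios
#'
#' Elasticities estimated from the full estimation window, from the most
#' recent 15 and 10 years, and two policy scenarios in which the
#' recent-10-year elasticities decline linearly over the horizon for total
#' drops of 10% and 20%.
#'
#' @return Data frame with columns `label`, `window_years` (NA = full
#'   window) and `decline`.
#' @export
default_scenarios <- function() {
  data.frame(
    label = c("full_window", "recent_15y", "recent_10y",
              "drop_10pct", "drop_20pct"),
    window_years = c(NA, 15, 10, 10, 10),
    decline = c(0, 0, 0, 0.10, 0.20),
    stringsAsFactors = FALSE)
}

# deterministic thinning (or seeded resampling) to exactly n_draws draws
thin_to <- function(n_have, n_want) {
  if (n_have >= n_want) {
    floor(seq(1, n_have, length.out = n_want))
  } else {
    sample.int(n_have, n_want, replace = TRUE)
  }
}

#' Run elasticity-draw forecasts under sensitivity scenarios
#'
#' For each scenario, fits (or reuses) the hierarchical model on the
#' scenario's estimation window, takes `n_draws` elasticity draws per country
#' from the posterior (deterministic thinning; seeded resampling with
#' replacement if fewer draws are retained), projects every country's
#' prevalence along its income-growth path with the scenario's decline ramp,
#' and aggregates across countries.
#'
#' @param panel validated panel.
#' @param moderators standardized moderator table.
#' @param projections projection table (see [read_projections()]).
#' @param scenarios scenario data frame (see [default_scenarios()]).
#' @param stratum stratum to forecast.
#' @param selected optional moderator subset passed to [run_gibbs()].
#' @param priors,mcmc estimation settings for the window fits.
#' @param n_draws elasticity draws per country (default 1000).
#' @param seed seed for draw resampling.
#' @param fits optional named list of prefitted `posterior_draws` keyed by
#'   window label (`"full"` or the window length), to skip refitting.
#' @return List of class `scenario_forecasts`: `table` (per-scenario average
#'   annual growth in percent with 95% prediction intervals) and `results`
#'   (named list of `forecast_result`).
#' @export
run_scenarios <- function(panel, moderators, projections,
                          scenarios = default_scenarios(),
                          stratum = "overall", selected = NULL,
                          priors = prior_config(), mcmc = mcmc_config(),
                          n_draws = 1000, seed = 1L, fits = NULL) {
  last_year <- max(panel$year)
  sub <- panel[panel$stratum == stratum & panel$year == last_year, ]
  start_prev <- setNames(sub$prevalence, sub$country)
  countries <- sort(names(start_prev))
  start_prev <- start_prev[countries]

  proj_by_country <- split(as.data.frame(projections), projections$country)
  missing_proj <- setdiff(countries, names(proj_by_country))
  if (length(missing_proj) > 0) {
    stop("no income projections for country(ies): ",
         paste(utils::head(missing_proj, 10L), collapse = ", "), call. = FALSE)
  }

  window_key <- ifelse(is.na(scenarios$window_years), "full",
                       as.character(scenarios$window_years))
  if (is.null(fits)) fits <- list()
  for (wk in unique(window_key)) {
    if (!is.null(fits[[wk]])) next
    wpanel <- panel
    if (wk != "full") {
      w <- as.integer(wk)
      if (w < 3) stop("estimation window too short to fit (< 3 years)",
                      call. = FALSE)
      keep <- panel$year > last_year - w
      wpanel <- validate_panel(as.data.frame(panel[keep, , drop = FALSE]))
    }
    fits[[wk]] <- run_gibbs(wpanel, moderators, stratum = stratum,
                            selected = selected, priors = priors, mcmc = mcmc)
  }

  year_grid <- sort(unique(projections$year))
  is_bridge <- vapply(year_grid, function(y) {
    any(projections$is_bridge[projections$year == y])
  }, logical(1))

  results <- list()
  rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    fit <- fits[[window_key[i]]]
    beta <- fit$delta[, , "beta", drop = FALSE]
    dim(beta) <- dim(fit$delta)[1:2]
    colnames(beta) <- fit$countries
    set.seed(seed + i)
    idx <- thin_to(nrow(beta), n_draws)
    ramp <- apply_ramp(sc$decline, sum(!is_bridge))
    trajs <- lapply(countries, function(cc) {
      gp <- proj_by_country[[cc]]
      project_country(start_prev[[cc]], beta[idx, cc], gp, ramp = ramp)
    })
    names(trajs) <- countries
    res <- aggregate_forecast(trajs, start_prev, is_bridge)
    results[[sc$label]] <- res
    rows[[i]] <- data.frame(scenario = sc$label,
                            growth_pct = res$growth$mean,
                            lower = res$growth$lower,
                            upper = res$growth$upper,
                            growth_of_mean_pct = res$growth$of_mean_trajectory,
                            n_clamped = res$n_clamped,
                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), results = results,
                 n_draws = n_draws, stratum = stratum),
            class = "scenario_forecasts")
}
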