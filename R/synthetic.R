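#' Configuration for the synthetic panel generator
#'
#' Defines the generating process the estimation modules assume: a log-log
#' first stage `ln(prev) = alpha_c + beta_c ln(gdppc) + noise` with
#' country-specific coefficients drawn from a second-stage regression on
#' standardized moderators, `(alpha_c, beta_c) = (X_c' theta_alpha,
#' X_c' theta_beta) + MVN(0, Sigma)`. GDP per capita follows a geometric
#' trajectory with country-specific drift and Gaussian log-shocks.
#'
#' The default true mean elasticity (the intercept of `theta_beta`) is 1.2.
#' The default `theta_alpha` intercept is set low (-13) so that, with the
#' wide default income spread (log-sd 1.5 across countries), simulated
#' prevalence stays inside (0, 100) with a rejection-redraw rate well under
#' 1%; every downstream estimand is invariant to this level shift.
#'
#' @param n_countries number of countries (default 147).
#' @param years calendar years of the panel (default 1975:2014).
#' @param strata strata to simulate; each stratum draws its own coefficient
#'   pair from the shared second stage.
#' @param n_moderators number of moderator variables, assigned to the five
#'   dimensions round-robin (default 10, two per dimension).
#' @param moderator_rho exchangeable correlation among continuous moderators.
#' @param moderator_cor optional full correlation matrix for the continuous
#'   moderators (overrides `moderator_rho`).
#' @param dummy_dimensions dimensions whose moderators are 0/1 dummies
#'   (default `"health_policy"`, mirroring tobacco-warning-law style
#'   indicators).
#' @param dummy_prob Bernoulli probability for dummy moderator values.
#' @param theta_alpha,theta_beta true second-stage coefficient vectors
#'   (intercept first, then one coefficient per moderator).
#' @param Sigma 2x2 covariance of the country-level coefficient deviations.
#' @param sigma_y observation noise sd on the log-prevalence scale.
#' @param gdppc_meanlog,gdppc_sdlog log-normal start-level distribution of
#'   GDP per capita.
#' @param growth_mean,growth_sd per-country mean annual log-growth of GDP per
#'   capita, `g_c ~ N(growth_mean, growth_sd^2)`.
#' @param shock_sd sd of i.i.d. annual log-growth shocks.
#' @param bridge_years,horizon_years years covered by the income projection
#'   table: actual-growth bridge years then the projection horizon.
#' @param max_redraws per-country cap on rejection redraws before the
#'   configuration is declared infeasible.
#' @param seed default seed used when none is passed to the generators.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_countries = 147,
                             years = 1975:2014,
                             strata = c("male", "female", "overall"),
                             n_moderators = 10,
                             moderator_rho = 0.2,
                             moderator_cor = NULL,
                             dummy_dimensions = "health_policy",
                             dummy_prob = 0.5,
                             theta_alpha = NULL,
                             theta_beta = NULL,
                             Sigma = diag(c(0.3^2, 0.15^2)),
                             sigma_y = 0.05,
                             gdppc_meanlog = 8.0,
                             gdppc_sdlog = 1.5,
                             growth_mean = 0.02,
                             growth_sd = 0.01,
                             shock_sd = 0.02,
                             bridge_years = 2015:2018,
                             horizon_years = 2019:2024,
                             max_redraws = 1000,
                             seed = 1L) {
  if (n_moderators < 5) {
    stop("need at least one moderator per dimension (n_moderators >= 5)",
         call. = FALSE)
  }
  if (length(years) < 3) stop("need at least 3 years", call. = FALSE)
  if (sigma_y < 0) stop("sigma_y must be non-negative", call. = FALSE)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("Sigma must be symmetric positive semi-definite", call. = FALSE)
  }
  k <- n_moderators
  if (is.null(theta_alpha)) {
    theta_alpha <- c(-13, 0.25, -0.20, rep(0, k - 2))
  }
  if (is.null(theta_beta)) {
    theta_beta <- c(1.2, 0.05, -0.06, -0.05, 0.01, rep(0, k - 4))
  }
  if (length(theta_alpha) != k + 1 || length(theta_beta) != k + 1) {
    stop("theta vectors must have length 1 + n_moderators", call. = FALSE)
  }
  structure(list(n_countries = n_countries, years = as.integer(years),
                 strata = strata, n_moderators = k,
                 moderator_rho = moderator_rho, moderator_cor = moderator_cor,
                 dummy_dimensions = dummy_dimensions, dummy_prob = dummy_prob,
                 theta_alpha = theta_alpha, theta_beta = theta_beta,
                 Sigma = Sigma, sigma_y = sigma_y,
                 gdppc_meanlog = gdppc_meanlog, gdppc_sdlog = gdppc_sdlog,
                 growth_mean = growth_mean, growth_sd = growth_sd,
                 shock_sd = shock_sd,
                 bridge_years = as.integer(bridge_years),
                 horizon_years = as.integer(horizon_years),
                 max_redraws = max_redraws, seed = seed),
            class = "generator_config")
}

synthetic_country_ids <- function(n) sprintf("C%03d", seq_len(n))

# draw n rows from MVN(0, Sigma); tolerates a (semi-)definite Sigma so the
# noiseless Sigma = 0 identifiability check is representable
rmvn0 <- function(n, Sigma) {
  p <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, p))
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  matrix(rnorm(n * p), n, p) %*% t(L)
}

#' Generate a synthetic moderator table
#'
#' Continuous moderators are drawn from a multivariate normal with the
#' configured correlation structure (standard-normal marginals); dummy
#' moderators are Bernoulli. Dimensions are assigned round-robin
#' (globalization, demographic, economic, labor, health_policy, ...).
#'
#' @param config [generator_config()].
#' @param seed integer seed.
#' @return Moderator table (long format, unstandardized); pass through
#'   [standardize_moderators()] before the second stage.
#' @export
generate_moderators <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$n_moderators
  vars <- sprintf("m%02d", seq_len(k))
  dims <- rep_len(MODERATOR_DIMENSIONS, k)
  is_dummy <- dims %in% config$dummy_dimensions
  n <- config$n_countries
  countries <- synthetic_country_ids(n)

  m_cont <- sum(!is_dummy)
  if (is.null(config$moderator_cor)) {
    R <- matrix(config$moderator_rho, m_cont, m_cont)
    diag(R) <- 1
  } else {
    R <- as.matrix(config$moderator_cor)
    if (nrow(R) != m_cont) {
      stop("moderator_cor must be ", m_cont, " x ", m_cont, call. = FALSE)
    }
  }
  L <- tryCatch(chol(R),
                error = function(e) stop("moderator correlation matrix is not positive definite",
                                         call. = FALSE))
  set.seed(seed)
  cont <- matrix(rnorm(n * m_cont), n, m_cont) %*% L
  vals <- matrix(NA_real_, n, k)
  vals[, !is_dummy] <- cont
  for (j in which(is_dummy)) {
    vals[, j] <- rbinom(n, 1L, config$dummy_prob)
  }
  as_moderator_table(data.frame(
    country = rep(countries, times = k),
    variable = rep(vars, each = n),
    dimension = rep(dims, each = n),
    is_dummy = rep(is_dummy, each = n),
    value = as.vector(vals),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic country-year panel with recorded ground truth
#'
#' For each country and stratum, draws the coefficient pair from the second
#' stage, simulates a geometric GDP-per-capita trajectory, and sets
#' `ln(prevalence) = alpha + beta * ln(gdppc) + N(0, sigma_y^2)`. A country
#' whose simulated prevalence exits (0, 100) anywhere is rejected and fully
#' redrawn (no truncation, which would distort the log-log structure); the
#' redraw count is recorded in the truth object.
#'
#' @param config [generator_config()].
#' @param moderators standardized moderator table covering the configured
#'   countries (continuous variables must be z-scored).
#' @param seed integer seed.
#' @return List with elements `panel` (validated panel) and `truth`
#'   (class `synthetic_truth`: per-country-stratum true coefficients, the
#'   theta vectors, `Sigma`, `sigma_y`, the moderator matrix used, and the
#'   redraw count).
#' @export
generate_panel <- function(config, moderators, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  countries <- synthetic_country_ids(config$n_countries)
  X <- moderator_matrix(moderators, countries = countries, intercept = TRUE)
  is_dummy <- attr(X, "is_dummy")
  cont <- X[, !is_dummy & colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(cont) > 0) {
    mu <- colMeans(cont)
    s <- apply(cont, 2, sd)
    if (any(abs(mu) > 1e-8) || any(abs(s - 1) > 1e-6)) {
      stop("continuous moderators must be standardized before panel generation",
           call. = FALSE)
    }
  }
  if (ncol(X) != length(config$theta_alpha)) {
    stop("moderator count does not match theta vector length", call. = FALSE)
  }
  mean_alpha <- drop(X %*% config$theta_alpha)
  mean_beta <- drop(X %*% config$theta_beta)

  years <- config$years
  T_len <- length(years)
  strata <- config$strata
  set.seed(seed)

  total_redraws <- 0L
  rows <- vector("list", length(countries))
  truth_rows <- vector("list", length(countries))
  for (i in seq_along(countries)) {
    tries <- 0L
    repeat {
      lng0 <- rnorm(1, config$gdppc_meanlog, config$gdppc_sdlog)
      drift <- rnorm(1, config$growth_mean, config$growth_sd)
      shocks <- rnorm(T_len - 1, 0, config$shock_sd)
      lng <- lng0 + c(0, cumsum(drift + shocks))
      dev <- rmvn0(length(strata), config$Sigma)
      alpha <- mean_alpha[i] + dev[, 1]
      beta <- mean_beta[i] + dev[, 2]
      lnprev <- rep(alpha, each = T_len) + rep(beta, each = T_len) * lng +
        rnorm(T_len * length(strata), 0, config$sigma_y)
      prev <- exp(lnprev)
      if (all(prev > 0 & prev < 100)) break
      tries <- tries + 1L
      if (tries > config$max_redraws) {
        stop("generator configuration infeasible: country ", countries[i],
             " exceeded ", config$max_redraws, " redraws", call. = FALSE)
      }
    }
    total_redraws <- total_redraws + tries
    rows[[i]] <- data.frame(
      country = countries[i],
      year = rep(years, times = length(strata)),
      stratum = rep(strata, each = T_len),
      prevalence = prev,
      gdppc = rep(exp(lng), times = length(strata)),
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      country = countries[i], stratum = strata,
      alpha = alpha, beta = beta, stringsAsFactors = FALSE)
  }
  panel <- validate_panel(do.call(rbind, rows))
  truth <- structure(list(
    coefficients = do.call(rbind, truth_rows),
    theta_alpha = setNames(config$theta_alpha, colnames(X)),
    theta_beta = setNames(config$theta_beta, colnames(X)),
    Sigma = config$Sigma, sigma_y = config$sigma_y,
    moderator_matrix = X, n_redraws = total_redraws,
    seed = seed), class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Generate synthetic income growth projections
#'
#' Per-country annual GDP-per-capita growth in percent over the bridge and
#' horizon years, drawn from the configured growth law: country drift
#' `N(growth_mean, growth_sd^2)` plus i.i.d. annual shocks
#' `N(0, shock_sd^2)`, reported as `100 * (drift + shock)`.
#'
#' @param config [generator_config()].
#' @param seed integer seed.
#' @return Projection table (see [read_projections()]).
#' @export
generate_projections <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  countries <- synthetic_country_ids(config$n_countries)
  years <- c(config$bridge_years, config$horizon_years)
  is_bridge <- years %in% config$bridge_years
  set.seed(seed)
  res <- lapply(countries, function(cc) {
    drift <- rnorm(1, config$growth_mean, config$growth_sd)
    g <- 100 * (drift + rnorm(length(years), 0, config$shock_sd))
    data.frame(country = cc, year = years, growth_pct = g,
               is_bridge = is_bridge, stringsAsFactors = FALSE)
  })
  as_projections(do.call(rbind, res))
}

#' Derive income-group / region assignments for a synthetic panel
#'
#' Classifies countries into the four income groups by quartile of their
#' final-year GDP per capita and assigns six synthetic regions round-robin.
#' Deterministic given the panel.
#'
#' @param panel validated panel.
#' @return Group table (see [read_groups()]).
#' @export
generate_groups <- function(panel) {
  last_year <- max(panel$year)
  sub <- panel[panel$year == last_year, ]
  g <- tapply(sub$gdppc, sub$country, mean)
  q <- quantile(g, probs = c(0.25, 0.5, 0.75))
  grp <- cut(g, breaks = c(-Inf, q, Inf),
             labels = c("low", "lower_middle", "upper_middle", "high"))
  countries <- names(g)
  data.frame(country = countries,
             income_group = as.character(grp),
             region = rep_len(sprintf("region_%d", 1:6), length(countries)),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the four CSV inputs of the analysis pipeline (panel, moderators,
#' projections, groups) plus a JSON sidecar with the generating truth.
#' Moderators are written standardized, as the second stage consumes them.
#'
#' @param config [generator_config()].
#' @param dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_dataset <- function(config, dir, seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mods <- standardize_moderators(generate_moderators(config, seed = seed))
  gen <- generate_panel(config, mods, seed = seed + 1L)
  proj <- generate_projections(config, seed = seed + 2L)
  groups <- generate_groups(gen$panel)
  paths <- list(panel = file.path(dir, "panel.csv"),
                moderators = file.path(dir, "moderators.csv"),
                projections = file.path(dir, "projections.csv"),
                groups = file.path(dir, "groups.csv"),
                truth = file.path(dir, "truth.json"))
  write_panel(gen$panel, paths$panel)
  write_moderators(mods, paths$moderators)
  write_projections(proj, paths$projections)
  write_groups(groups, paths$groups)
  truth <- gen$truth
  jsonlite::write_json(list(
    coefficients = truth$coefficients,
    theta_alpha = as.list(truth$theta_alpha),
    theta_beta = as.list(truth$theta_beta),
    Sigma = truth$Sigma, sigma_y = truth$sigma_y,
    n_redraws = truth$n_redraws, seed = truth$seed),
    paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
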