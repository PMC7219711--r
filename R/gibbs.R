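#' Weakly-informative conjugate prior configuration
#'
#' Priors for the hierarchical model: a flat normal prior on the second-stage
#' coefficient matrix with scalar precision `A`, an inverse-Wishart prior on
#' the 2x2 coefficient covariance, and scale-inverse-chi-square priors on the
#' per-country error variances (log scale).
#'
#' @param A prior precision on the second-stage coefficients (default 0.01,
#'   i.e. prior sd 10 per coefficient).
#' @param nu inverse-Wishart degrees of freedom (default `dim + 3 = 5`).
#' @param V inverse-Wishart scale matrix (default `nu * I`).
#' @param nu0 error-variance prior degrees of freedom.
#' @param s02 error-variance prior scale on the log-prevalence scale
#'   (default 0.01, i.e. a prior residual sd of 0.1; national prevalence
#'   series are tight on the log scale, and a larger scale would let the
#'   prior sum of squares `nu0 * s02` swamp the within-country residual
#'   information).
#' @return List of class `prior_config`.
#' @export
prior_config <- function(A = 0.01, nu = 5, V = NULL, nu0 = 3, s02 = 0.01) {
  if (A <= 0) stop("A must be positive", call. = FALSE)
  if (nu <= 3) stop("nu must exceed dim + 1 = 3", call. = FALSE)
  if (is.null(V)) V <- nu * diag(2)
  V <- as.matrix(V)
  if (nu0 <= 0 || s02 <= 0) stop("nu0 and s02 must be positive", call. = FALSE)
  structure(list(A = A, nu = nu, V = V, nu0 = nu0, s02 = s02),
            class = "prior_config")
}

#' MCMC run-length configuration
#'
#' Defaults mirror common practice for this model class: 50,000 iterations,
#' the first 30,000 (raw iterations) discarded as burn-in, and every 10th
#' subsequent draw retained, giving 2,000 retained draws.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in burn-in length in raw iterations (`< n_iter`).
#' @param thin thinning interval applied after burn-in.
#' @param seed integer RNG seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 50000, burn_in = 30000, thin = 10, seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be at least 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

# per-country sufficient statistics of the log-log first stage
panel_suffstats <- function(panel, stratum) {
  sub <- panel[panel$stratum == stratum, , drop = FALSE]
  if (nrow(sub) == 0) stop("no observations for stratum ", stratum, call. = FALSE)
  countries <- sort(unique(sub$country))
  N <- length(countries)
  WtW <- array(0, c(2, 2, N))
  Wty <- matrix(0, 2, N)
  yty <- numeric(N)
  Tobs <- numeric(N)
  for (i in seq_len(N)) {
    d <- sub[sub$country == countries[i], ]
    W <- cbind(1, log(d$gdppc))
    y <- log(d$prevalence)
    WtW[, , i] <- crossprod(W)
    Wty[, i] <- crossprod(W, y)
    yty[i] <- sum(y^2)
    Tobs[i] <- nrow(d)
  }
  list(countries = countries, WtW = WtW, Wty = Wty, yty = yty, Tobs = Tobs)
}

#' Per-country OLS intercepts and elasticities (log-log first stage)
#'
#' The fast classical counterpart of the hierarchical fit: an ordinary
#' least-squares regression of log prevalence on log GDP per capita for each
#' country. Used as the response in moderator forward selection and as a
#' reference in shrinkage diagnostics.
#'
#' @param panel validated panel.
#' @param stratum stratum to fit.
#' @return Data frame with columns `country`, `alpha`, `beta`.
#' @export
ols_elasticities <- function(panel, stratum = "overall") {
  ss <- panel_suffstats(panel, stratum)
  est <- vapply(seq_along(ss$countries), function(i) {
    drop(solve(ss$WtW[, , i], ss$Wty[, i]))
  }, numeric(2))
  data.frame(country = ss$countries, alpha = est[1, ], beta = est[2, ],
             stringsAsFactors = FALSE)
}

#' Fit the two-stage hierarchical model by Gibbs sampling
#'
#' Jointly estimates the country-level log-log regressions and the
#' second-stage moderator regression by cycling four conjugate blocks:
#' (1) each country's coefficient pair from its multivariate-normal full
#' conditional (least-squares information shrunk toward the second-stage
#' prediction `Delta' x_c` with covariance `Sigma`); (2) each country's error
#' variance from its inverse-gamma full conditional; (3) the second-stage
#' coefficient matrix from its matrix-normal full conditional; (4) `Sigma`
#' from its inverse-Wishart full conditional. Burn-in is discarded in raw
#' iterations, then thinning is applied.
#'
#' @param panel validated panel.
#' @param moderators standardized moderator table covering every panel
#'   country.
#' @param stratum stratum to fit (the male, female and overall strata are
#'   modelled separately).
#' @param selected optional character vector of moderator variables to use
#'   (default: all variables in `moderators`).
#' @param priors [prior_config()].
#' @param mcmc [mcmc_config()].
#' @return Object of class `posterior_draws` with arrays `delta`
#'   (draw x country x 2), `Delta` (draw x coefficient x 2, columns for the
#'   intercept and elasticity equations), `Sigma` (draw x 2 x 2), `sigma2`
#'   (draw x country), plus country ids, coefficient names and the configs.
#' @export
run_gibbs <- function(panel, moderators, stratum = "overall", selected = NULL,
                      priors = prior_config(), mcmc = mcmc_config()) {
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))
  ss <- panel_suffstats(panel, stratum)
  mods <- as_moderator_table(moderators)
  if (!is.null(selected)) {
    unknown <- setdiff(selected, unique(mods$variable))
    if (length(unknown) > 0) {
      stop("selected moderator(s) not in table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mods <- mods[mods$variable %in% selected, , drop = FALSE]
  }
  uncovered <- setdiff(ss$countries, unique(mods$country))
  if (length(uncovered) > 0) {
    stop("moderator table does not cover panel country(ies): ",
         paste(utils::head(uncovered, 10L), collapse = ", "), call. = FALSE)
  }
  X <- moderator_matrix(mods, countries = ss$countries, intercept = TRUE)
  k <- ncol(X)
  Deltabar <- matrix(0, k, 2)

  set.seed(mcmc$seed)
  res <- cpp_gibbs(ss$WtW, ss$Wty, ss$yty, ss$Tobs, X,
                   priors$A, Deltabar, priors$nu, priors$V,
                   priors$nu0, priors$s02,
                   mcmc$n_iter, mcmc$burn_in, mcmc$thin)

  n_keep <- res$n_keep
  # cubes arrive as (dim1, dim2, draw); reorder draw-first
  delta <- aperm(res$delta, c(3, 2, 1))      # draw x country x 2
  Delta <- aperm(res$Delta, c(3, 1, 2))      # draw x coef x 2
  Sigma <- aperm(res$Sigma, c(3, 1, 2))      # draw x 2 x 2
  dimnames(delta) <- list(NULL, ss$countries, c("alpha", "beta"))
  dimnames(Delta) <- list(NULL, colnames(X), c("alpha", "beta"))
  structure(list(delta = delta, Delta = Delta, Sigma = Sigma,
                 sigma2 = t(res$sigma2),
                 countries = ss$countries, coef_names = colnames(X),
                 stratum = stratum, n_draws = n_keep,
                 priors = priors, mcmc = mcmc),
            class = "posterior_draws")
}

#' Summarize posterior draws into elasticity estimates
#'
#' Posterior means and equal-tailed 95% credible intervals for: each
#' country's elasticity; the cross-country mean elasticity (the average over
#' countries is taken within each draw, so its interval reflects posterior
#' uncertainty about the mean); and the second-stage coefficients, flagged
#' significant when the interval excludes zero.
#'
#' @param draws `posterior_draws` object.
#' @param prob interval mass (default 0.95).
#' @return Object of class `elasticity_summary` with data frames
#'   `elasticities` (country, mean, lower, upper), `mean_elasticity`,
#'   and `theta` (equation, variable, estimate, lower, upper, significant).
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_draws < 100) {
    warning("fewer than 100 retained draws; posterior summaries are imprecise",
            call. = FALSE)
  }
  a <- (1 - prob) / 2
  qs <- c(a, 1 - a)
  beta <- draws$delta[, , "beta", drop = FALSE]
  dim(beta) <- dim(draws$delta)[1:2]
  el <- data.frame(
    country = draws$countries,
    mean = colMeans(beta),
    lower = apply(beta, 2, quantile, probs = qs[1]),
    upper = apply(beta, 2, quantile, probs = qs[2]),
    stringsAsFactors = FALSE, row.names = NULL)
  mean_chain <- rowMeans(beta)
  mean_el <- data.frame(mean = mean(mean_chain),
                        lower = unname(quantile(mean_chain, qs[1])),
                        upper = unname(quantile(mean_chain, qs[2])))
  theta <- do.call(rbind, lapply(c("alpha", "beta"), function(eq) {
    M <- draws$Delta[, , eq, drop = FALSE]
    dim(M) <- dim(draws$Delta)[1:2]
    data.frame(equation = eq, variable = draws$coef_names,
               estimate = colMeans(M),
               lower = apply(M, 2, quantile, probs = qs[1]),
               upper = apply(M, 2, quantile, probs = qs[2]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  theta$significant <- theta$lower > 0 | theta$upper < 0
  structure(list(elasticities = el, mean_elasticity = mean_el, theta = theta,
                 stratum = draws$stratum, n_draws = draws$n_draws,
                 prob = prob),
            class = "elasticity_summary")
}

#' @export
print.elasticity_summary <- function(x, ...) {
  cat("Two-stage hierarchical model summary (stratum: ", x$stratum,
      ", ", x$n_draws, " draws)\n", sep = "")
  cat(sprintf("Cross-country mean elasticity: %.3f (%.3f, %.3f)\n",
              x$mean_elasticity$mean, x$mean_elasticity$lower,
              x$mean_elasticity$upper))
  cat("\nSecond-stage coefficients (elasticity equation):\n")
  tb <- x$theta[x$theta$equation == "beta", ]
  print(data.frame(variable = tb$variable,
                   estimate = round(tb$estimate, 3),
                   lower = round(tb$lower, 3), upper = round(tb$upper, 3),
                   significant = tb$significant), row.names = FALSE)
  invisible(x)
}
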