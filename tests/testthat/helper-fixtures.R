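# small deterministic fixtures built in code

# three-country, five-year panel following an exact log-log law
tiny_panel_df <- function(noise_sd = 0, seed = 42) {
  set.seed(seed)
  countries <- c("AAA", "BBB", "CCC")
  alpha <- c(-6, -9, -5.5)
  beta <- c(1.0, 1.4, 0.8)
  years <- 2000:2004
  gdppc <- list(AAA = 1000 * 1.02^(0:4), BBB = 5000 * 1.03^(0:4),
                CCC = 20000 * 1.01^(0:4))
  do.call(rbind, lapply(seq_along(countries), function(i) {
    g <- gdppc[[i]]
    lp <- alpha[i] + beta[i] * log(g) + rnorm(length(g), 0, noise_sd)
    data.frame(country = countries[i], year = years, stratum = "overall",
               prevalence = exp(lp), gdppc = g, stringsAsFactors = FALSE)
  }))
}

tiny_truth <- function() {
  list(alpha = c(AAA = -6, BBB = -9, CCC = -5.5),
       beta = c(AAA = 1.0, BBB = 1.4, CCC = 0.8))
}

# hand-built moderator table: one variable per dimension, n countries
tiny_moderators <- function(n = 20, seed = 7) {
  set.seed(seed)
  countries <- sprintf("C%03d", seq_len(n))
  vars <- c("glob1", "demo1", "econ1", "labor1", "policy1")
  dims <- c("globalization", "demographic", "economic", "labor",
            "health_policy")
  do.call(rbind, lapply(seq_along(vars), function(j) {
    data.frame(country = countries, variable = vars[j], dimension = dims[j],
               is_dummy = dims[j] == "health_policy",
               value = if (dims[j] == "health_policy") {
                 rbinom(n, 1, 0.5)
               } else rnorm(n),
               stringsAsFactors = FALSE)
  }))
}

# small generator configuration for quick end-to-end runs
quick_config <- function(...) {
  generator_config(n_countries = 25, years = 1990:2004, strata = "overall",
                   ...)
}

short_mcmc <- function(seed = 1L) {
  mcmc_config(n_iter = 1500, burn_in = 500, thin = 2, seed = seed)
}

# sufficient statistics for a hand-built multi-country regression problem
toy_problem <- function(N = 5, T = 8, seed = 99) {
  set.seed(seed)
  WtW <- array(0, c(2, 2, N)); Wty <- matrix(0, 2, N)
  yty <- numeric(N); Tobs <- rep(T, N)
  for (c in seq_len(N)) {
    W <- cbind(1, rnorm(T, 8, 1))
    y <- rnorm(T, -1 + 0.5 * W[, 2], 0.3)
    WtW[, , c] <- crossprod(W); Wty[, c] <- crossprod(W, y)
    yty[c] <- sum(y^2)
  }
  list(WtW = WtW, Wty = Wty, yty = yty, Tobs = Tobs, N = N, T = T)
}
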