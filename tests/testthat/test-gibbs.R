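test_that("identical data, priors and seed give identical retained draws", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 4))
  gen <- generate_panel(cfg, mods, seed = 5)
  f1 <- run_gibbs(gen$panel, mods, mcmc = short_mcmc(seed = 11))
  f2 <- run_gibbs(gen$panel, mods, mcmc = short_mcmc(seed = 11))
  expect_identical(f1$delta, f2$delta)
  expect_identical(f1$Delta, f2$Delta)
  expect_identical(f1$Sigma, f2$Sigma)
  f3 <- run_gibbs(gen$panel, mods, mcmc = short_mcmc(seed = 12))
  expect_false(identical(f1$delta, f3$delta))
})

test_that("retained draw count follows (n_iter - burn_in) / thin", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 4))
  gen <- generate_panel(cfg, mods, seed = 5)
  fit <- run_gibbs(gen$panel, mods,
                   mcmc = mcmc_config(n_iter = 1000, burn_in = 600,
                                      thin = 4, seed = 1))
  expect_equal(fit$n_draws, 100)
  expect_equal(dim(fit$delta), c(100, cfg$n_countries, 2))
  # every retained Sigma draw is symmetric positive definite
  ev <- apply(fit$Sigma, 1, function(S) {
    min(eigen(matrix(S, 2, 2), symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(ev > 0))
  expect_true(all(fit$sigma2 > 0))
})

test_that("posterior concentrates on truth for noiseless panels", {
  cfg <- quick_config(sigma_y = 0, Sigma = matrix(0, 2, 2))
  mods <- standardize_moderators(generate_moderators(cfg, seed = 2))
  gen <- generate_panel(cfg, mods, seed = 3)
  fit <- run_gibbs(gen$panel, mods,
                   priors = prior_config(nu0 = 1, s02 = 1e-6),
                   mcmc = mcmc_config(n_iter = 3000, burn_in = 1500,
                                      thin = 3, seed = 7))
  beta_hat <- colMeans(fit$delta[, , "beta"])
  truth <- setNames(gen$truth$coefficients$beta, gen$truth$coefficients$country)
  expect_lt(max(abs(beta_hat - truth[names(beta_hat)])), 1e-3)
})

test_that("country coefficients shrink from OLS toward the prior plane", {
  # diagonal case (centred regressor, diagonal Sigma): componentwise
  # betweenness of the conditional mean is exact
  T <- 10
  x <- seq(-2, 2, length.out = T)  # centred: W'W diagonal
  W <- cbind(1, x)
  set.seed(21)
  y <- 1 + 2 * x + rnorm(T, 0, 0.5)
  WtW <- array(crossprod(W), c(2, 2, 1))
  Wty <- matrix(crossprod(W, y), 2, 1)
  ols <- solve(WtW[, , 1], Wty[, 1])
  prior_mean <- matrix(c(0, 0), 2, 1)
  Sigma <- diag(c(0.5, 0.5))
  draws <- replicate(4000, obelast:::cpp_draw_delta(
    WtW, Wty, sigma2 = 0.25, Sigma = Sigma, prior_mean = prior_mean))
  m <- rowMeans(draws[, 1, ])
  se <- apply(draws[, 1, ], 1, sd) / sqrt(4000)
  for (j in 1:2) {
    lo <- min(prior_mean[j], ols[j]) - 3 * se[j]
    hi <- max(prior_mean[j], ols[j]) + 3 * se[j]
    expect_gt(m[j], lo)
    expect_lt(m[j], hi)
  }
  # and with a tight likelihood the mean must be near OLS, not the prior
  draws2 <- replicate(2000, obelast:::cpp_draw_delta(
    WtW, Wty, sigma2 = 1e-6, Sigma = Sigma, prior_mean = prior_mean))
  expect_equal(rowMeans(draws2[, 1, ]), unname(ols), tolerance = 1e-2)
})

test_that("posterior summaries follow the draws", {
  # hand-built posterior_draws with known content
  nd <- 10000
  delta <- array(0, c(nd, 2, 2),
                 dimnames = list(NULL, c("A", "B"), c("alpha", "beta")))
  delta[, "A", "beta"] <- 1.5           # point mass
  set.seed(5)
  delta[, "B", "beta"] <- rnorm(nd)     # standard normal
  Delta <- array(rnorm(nd * 2 * 2, mean = rep(c(0.3, 3), each = nd)),
                 c(nd, 2, 2),
                 dimnames = list(NULL, c("(Intercept)", "m1"),
                                 c("alpha", "beta")))
  draws <- structure(list(delta = delta, Delta = Delta,
                          Sigma = array(diag(2), c(nd, 2, 2)),
                          sigma2 = matrix(1, nd, 2),
                          countries = c("A", "B"),
                          coef_names = c("(Intercept)", "m1"),
                          stratum = "overall", n_draws = nd,
                          priors = prior_config(), mcmc = mcmc_config()),
                     class = "posterior_draws")
  s <- summarize_posterior(draws)
  elA <- s$elasticities[s$elasticities$country == "A", ]
  expect_equal(elA$mean, 1.5)
  expect_equal(elA$lower, 1.5)
  expect_equal(elA$upper, 1.5)
  elB <- s$elasticities[s$elasticities$country == "B", ]
  expect_equal(elB$lower, -1.96, tolerance = 0.08)
  expect_equal(elB$upper, 1.96, tolerance = 0.08)
  # intervals excluding zero are flagged significant
  th <- s$theta
  expect_true(all(th$significant[th$variable == "m1"]))
  expect_true(all(th$lower <= th$estimate & th$estimate <= th$upper))
})

test_that("too few retained draws triggers a precision warning", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 4))
  gen <- generate_panel(cfg, mods, seed = 5)
  fit <- run_gibbs(gen$panel, mods,
                   mcmc = mcmc_config(n_iter = 300, burn_in = 200, thin = 2,
                                      seed = 1))
  expect_warning(summarize_posterior(fit), "fewer than 100")
})

test_that("unmatched countries in the moderator table are an error", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 4))
  gen <- generate_panel(cfg, mods, seed = 5)
  expect_error(run_gibbs(gen$panel, mods[mods$country != "C003", ]),
               "C003")
  expect_error(run_gibbs(gen$panel, mods, selected = "nope"), "nope")
})
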