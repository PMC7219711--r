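test_that("generation is fully determined by (config, seed)", {
  cfg <- quick_config()
  m1 <- generate_moderators(cfg, seed = 5)
  m2 <- generate_moderators(cfg, seed = 5)
  expect_identical(m1, m2)
  s1 <- standardize_moderators(m1)
  g1 <- generate_panel(cfg, s1, seed = 6)
  g2 <- generate_panel(cfg, s1, seed = 6)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$truth$coefficients, g2$truth$coefficients)
  p1 <- generate_projections(cfg, seed = 7)
  expect_identical(p1, generate_projections(cfg, seed = 7))
  expect_false(identical(g1$panel$prevalence,
                         generate_panel(cfg, s1, seed = 8)$panel$prevalence))
})

test_that("dummy probability zero yields all-zero dummy moderators", {
  cfg <- quick_config(dummy_prob = 0)
  mods <- generate_moderators(cfg, seed = 1)
  expect_true(all(mods$value[mods$is_dummy] == 0))
})

test_that("uncorrelated moderators have vanishing sample correlations", {
  cfg <- generator_config(n_countries = 500, n_moderators = 5,
                          moderator_rho = 0, dummy_dimensions = character(0))
  worst <- vapply(1:20, function(s) {
    X <- moderator_matrix(generate_moderators(cfg, seed = s))
    R <- cor(X)
    max(abs(R[upper.tri(R)]))
  }, numeric(1))
  expect_lt(max(worst), 0.15)
})

test_that("noiseless generation is exactly the second-stage plane", {
  cfg <- quick_config(sigma_y = 0, Sigma = matrix(0, 2, 2))
  mods <- standardize_moderators(generate_moderators(cfg, seed = 2))
  gen <- generate_panel(cfg, mods, seed = 3)
  X <- gen$truth$moderator_matrix
  expected_beta <- drop(X %*% gen$truth$theta_beta)
  expected_alpha <- drop(X %*% gen$truth$theta_alpha)
  ols <- ols_elasticities(gen$panel)
  expect_equal(ols$beta, unname(expected_beta[ols$country]), tolerance = 1e-10)
  expect_equal(ols$alpha, unname(expected_alpha[ols$country]), tolerance = 1e-10)
})

test_that("noiseless two-step pipeline recovers theta_beta exactly", {
  cfg <- quick_config(sigma_y = 0, Sigma = matrix(0, 2, 2))
  mods <- standardize_moderators(generate_moderators(cfg, seed = 2))
  gen <- generate_panel(cfg, mods, seed = 3)
  ols <- ols_elasticities(gen$panel)
  X <- moderator_matrix(mods, countries = ols$country, intercept = TRUE)
  theta_hat <- qr.coef(qr(X), ols$beta)
  expect_equal(unname(theta_hat), unname(gen$truth$theta_beta),
               tolerance = 1e-8)
})

test_that("default-config elasticities centre on the true mean", {
  cfg <- generator_config(strata = "overall")
  errs <- vapply(1:5, function(s) {
    mods <- standardize_moderators(generate_moderators(cfg, seed = s))
    gen <- generate_panel(cfg, mods, seed = 1000 + s)
    mean(ols_elasticities(gen$panel)$beta) - 1.2
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("rejection-redraw rate stays below 1% under the default config", {
  cfg <- generator_config(strata = "overall")
  redraws <- vapply(1:5, function(s) {
    mods <- standardize_moderators(generate_moderators(cfg, seed = s))
    generate_panel(cfg, mods, seed = 2000 + s)$truth$n_redraws
  }, numeric(1))
  expect_lt(sum(redraws) / (5 * cfg$n_countries), 0.01)
})

test_that("an infeasible configuration fails with a redraw error", {
  cfg <- quick_config(theta_alpha = c(50, rep(0, 10)), max_redraws = 5)
  mods <- standardize_moderators(generate_moderators(cfg, seed = 1))
  expect_error(generate_panel(cfg, mods, seed = 1), "infeasible")
})

test_that("projections cover bridge plus horizon with the configured law", {
  cfg <- quick_config(growth_sd = 0, shock_sd = 0, growth_mean = 0.02)
  proj <- generate_projections(cfg, seed = 1)
  expect_true(all(proj$growth_pct == 2))
  one <- proj[proj$country == "C001", ]
  expect_equal(one$year, 2015:2024)
  expect_equal(sum(!one$is_bridge), 6)  # 2019-2024 horizon
  expect_equal(sum(one$is_bridge), 4)   # 2015-2018 bridge
})

test_that("a written synthetic dataset reads back consistently", {
  cfg <- quick_config()
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(cfg, dir, seed = 10)
  panel <- read_panel(paths$panel)
  mods <- read_moderators(paths$moderators)
  proj <- read_projections(paths$projections)
  groups <- read_groups(paths$groups)
  gen <- generate_panel(cfg, standardize_moderators(
    generate_moderators(cfg, seed = 10)), seed = 11)
  expect_equal(panel$prevalence, gen$panel$prevalence, tolerance = 1e-12)
  expect_setequal(unique(mods$dimension), MODERATOR_DIMENSIONS)
  expect_equal(nrow(groups), cfg$n_countries)
  expect_equal(nrow(proj), cfg$n_countries * 10)
  expect_true(file.exists(paths$truth))
})
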