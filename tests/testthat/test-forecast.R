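test_that("the decline ramp interpolates linearly to its endpoint", {
  expect_equal(apply_ramp(0.2, 6)[6], 0.8)
  expect_equal(apply_ramp(0, 6), rep(1, 6))
  expect_equal(apply_ramp(0.1, 6)[3], 0.95)
  expect_equal(apply_ramp(0.2, 6, mode = "step"), rep(0.8, 6))
  expect_error(apply_ramp(1, 6), "d must be")
})

mk_path <- function(years, growth, bridge = rep(FALSE, length(years))) {
  data.frame(year = years, growth_pct = growth, is_bridge = bridge)
}

test_that("projection compounds elasticity times income growth", {
  path10 <- mk_path(2015:2024, rep(2, 10))
  # unit elasticity: prevalence grows exactly with income
  tr <- project_country(10, 1, path10)
  expect_equal(as.numeric(tr), 10 * 1.02^(1:10))
  # zero elasticity: flat
  expect_equal(as.numeric(project_country(10, 0, path10)), rep(10, 10))
  # beta = 1.5, g = 2%: 3% per year compounding
  tr <- project_country(10, 1.5, path10)
  expect_equal(unname(tr[1, 10]), 10 * 1.03^10)
  expect_equal(unname(round(tr[1, 10], 4)), 13.4392)
})

test_that("bridge-only paths reproduce pure actual-growth compounding", {
  path <- mk_path(2015:2018, rep(3, 4), bridge = rep(TRUE, 4))
  tr <- project_country(20, 2, path, ramp = numeric(0))
  expect_equal(as.numeric(tr), 20 * 1.06^(1:4))  # s = 1 in bridge years
})

test_that("trajectories clamp at the prevalence bounds with a counter", {
  path <- mk_path(2015:2024, rep(50, 10))
  tr <- project_country(90, 2, path)
  expect_true(all(tr <= 100))
  expect_gt(attr(tr, "n_clamped"), 0)
  path_neg <- mk_path(2015:2024, rep(-60, 10))
  tr2 <- project_country(5, 2, path_neg)
  expect_true(all(tr2 >= 0))
})

test_that("aggregation averages countries and degenerates correctly", {
  path <- mk_path(2019:2024, rep(2, 6))
  t1 <- project_country(10, c(1, 1), path)
  t2 <- project_country(20, c(1, 1), path)
  # flat countries at 10% and 20% aggregate to 15%
  flat <- mk_path(2019:2024, rep(0, 6))
  f1 <- project_country(10, c(1, 1), flat)
  f2 <- project_country(20, c(1, 1), flat)
  agg <- aggregate_forecast(list(A = f1, B = f2),
                            start_prev = c(A = 10, B = 20),
                            is_bridge = rep(FALSE, 6))
  expect_equal(unname(agg$mean), rep(15, 6))
  expect_equal(agg$growth$mean, 0)
  # one country: aggregate equals that country
  solo <- aggregate_forecast(list(A = t1), start_prev = c(A = 10),
                             is_bridge = rep(FALSE, 6))
  expect_equal(unname(solo$mean), unname(colMeans(t1)))
  # point-mass draws: zero band width
  expect_equal(solo$lower, solo$upper)
  # mean trajectory lies within the band
  expect_true(all(agg$lower <= agg$mean & agg$mean <= agg$upper))
  # mismatched year grids are an alignment error
  expect_error(aggregate_forecast(list(A = t1, B = f1[, 1:5]),
                                  c(A = 10, B = 10), rep(FALSE, 6)),
               "year grids")
})

test_that("scenario growth is non-increasing in the total decline", {
  path <- mk_path(2019:2024, rep(2.5, 6))
  set.seed(2)
  beta <- rnorm(400, 1.2, 0.2)
  growth <- vapply(c(0, 0.05, 0.1, 0.2), function(d) {
    tr <- project_country(12, beta, path, ramp = apply_ramp(d, 6))
    agg <- aggregate_forecast(list(A = tr), c(A = 12), rep(FALSE, 6))
    agg$growth$mean
  }, numeric(1))
  expect_true(all(diff(growth) <= 0))
})

test_that("run_scenarios produces the five ordered scenarios end to end", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 4))
  gen <- generate_panel(cfg, mods, seed = 5)
  proj <- generate_projections(cfg, seed = 6)
  sc <- run_scenarios(gen$panel, mods, proj, mcmc = short_mcmc(seed = 2),
                      n_draws = 150, seed = 3)
  expect_equal(sc$table$scenario, default_scenarios()$label)
  expect_lt(sc$table$growth_pct[sc$table$scenario == "drop_20pct"],
            sc$table$growth_pct[sc$table$scenario == "recent_10y"])
  expect_true(all(sc$table$lower <= sc$table$growth_pct &
                  sc$table$growth_pct <= sc$table$upper))
  # no clamping on a default-scale synthetic configuration
  expect_equal(sum(sc$table$n_clamped), 0)
  # windows shorter than 3 years cannot be fitted
  bad <- default_scenarios(); bad$window_years[2] <- 2
  expect_error(run_scenarios(gen$panel, mods, proj, scenarios = bad,
                             mcmc = short_mcmc(seed = 2)),
               "too short")
})
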