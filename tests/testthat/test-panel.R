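test_that("panel CSV round trip preserves a well-formed fixture", {
  df <- tiny_panel_df()
  # round to the representable text precision so equality can be exact
  df$prevalence <- signif(df$prevalence, 12)
  df$gdppc <- signif(df$gdppc, 12)
  panel <- validate_panel(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(length(unique(back$country)), 3)
  expect_identical(back$prevalence, panel$prevalence)
  expect_identical(back$gdppc, panel$gdppc)
  expect_identical(back$year, panel$year)
})

test_that("rows violating invariants are rejected with per-row reasons", {
  df <- tiny_panel_df()
  df$prevalence[2] <- 0
  df$gdppc[7] <- -5
  panel <- validate_panel(df)
  rej <- attr(panel, "rejected")
  expect_equal(sort(rej$reason),
               sort(c("non-positive prevalence", "non-positive gdppc")))
  expect_equal(nrow(panel), nrow(df) - 2)
  # a country-stratum left with <3 distinct years is dropped entirely
  df2 <- tiny_panel_df()[c(1:2, 6:15), ]
  panel2 <- validate_panel(df2)
  expect_false("AAA" %in% panel2$country)
  expect_true(any(grepl("fewer than 3",
                        attr(panel2, "rejected")$reason)))
})

test_that("duplicate keys and missing columns are hard errors", {
  df <- tiny_panel_df()
  expect_error(validate_panel(rbind(df, df[1, ])), "duplicate")
  expect_error(validate_panel(df[, -4]), "missing required column")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, 1:3], path, row.names = FALSE)
  expect_error(read_panel(path), "lacks column")
})

test_that("generator output survives a write-then-read round trip", {
  cfg <- quick_config()
  mods <- standardize_moderators(generate_moderators(cfg, seed = 3))
  gen <- generate_panel(cfg, mods, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(gen$panel, path)
  back <- read_panel(path)
  expect_equal(back$prevalence, gen$panel$prevalence, tolerance = 1e-12)
  expect_equal(back$gdppc, gen$panel$gdppc, tolerance = 1e-12)
  expect_identical(as.data.frame(back)[c("country", "year", "stratum")],
                   as.data.frame(gen$panel)[c("country", "year", "stratum")])
})

test_that("standardization z-scores continuous covariates and keeps dummies", {
  mods <- data.frame(
    country = rep(c("A", "B", "C"), 2),
    variable = rep(c("x", "d"), each = 3),
    dimension = rep(c("economic", "health_policy"), each = 3),
    is_dummy = rep(c(FALSE, TRUE), each = 3),
    value = c(1, 2, 3, 0, 1, 1), stringsAsFactors = FALSE)
  out <- standardize_moderators(mods)
  expect_equal(out$value[out$variable == "x"], c(-1, 0, 1))
  expect_equal(out$value[out$variable == "d"], c(0, 1, 1))
})

test_that("standardization is exact and idempotent on generated tables", {
  mods <- standardize_moderators(generate_moderators(quick_config(), seed = 9))
  X <- moderator_matrix(mods)
  cont <- X[, !attr(X, "is_dummy"), drop = FALSE]
  expect_lt(max(abs(colMeans(cont))), 1e-10)
  expect_lt(max(abs(apply(cont, 2, sd) - 1)), 1e-10)
  again <- standardize_moderators(mods)
  expect_equal(again$value, mods$value, tolerance = 1e-10)
})

test_that("zero-variance covariates are rejected by name", {
  mods <- tiny_moderators()
  mods$value[mods$variable == "econ1"] <- 5
  expect_error(standardize_moderators(mods), "econ1")
})

test_that("CAGR matches its definition and worked values", {
  expect_equal(compute_cagr(10, 10, 5), 0)
  expect_equal(compute_cagr(100, 121, 2), 10)
  expect_equal(round(compute_cagr(5.41, 17.51, 39), 2), 3.06)
  expect_error(compute_cagr(0, 10, 5), "positive")
  expect_error(compute_cagr(10, 5, 0), "at least 1")
})

test_that("CAGR is scale-invariant", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 1, 50); b <- runif(1, 1, 50)
    n <- sample(1:40, 1); k <- runif(1, 0.01, 100)
    expect_equal(compute_cagr(a, b, n), compute_cagr(k * a, k * b, n))
  }
})

test_that("group summaries average unweighted across countries", {
  df <- tiny_panel_df()
  panel <- validate_panel(df)
  groups <- data.frame(country = c("AAA", "BBB", "CCC"),
                       income_group = c("low", "low", "high"),
                       region = "region_1", stringsAsFactors = FALSE)
  panel$prevalence[panel$country == "AAA" & panel$year == 2000] <- 10
  panel$prevalence[panel$country == "BBB" & panel$year == 2000] <- 20
  gs <- group_summary(panel, groups, 2000)
  low <- gs[gs$income_group == "low", ]
  expect_equal(low$mean_prevalence, 15)
  expect_equal(low$n_countries, 2)
  high <- gs[gs$income_group == "high", ]
  expect_true(is.na(high$sd_prevalence))  # single-country group flagged
})

test_that("group summary warns when a year is missing for some country", {
  df <- tiny_panel_df()
  df <- df[!(df$country == "CCC" & df$year == 2000), ]
  panel <- validate_panel(df)
  groups <- data.frame(country = c("AAA", "BBB", "CCC"),
                       income_group = "high", region = "r",
                       stringsAsFactors = FALSE)
  expect_warning(group_summary(panel, groups, 2000), "CCC")
})
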