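#' Moderator dimension names
#'
#' The five macro-environmental dimensions into which country-level moderator
#' variables are organized: globalization orientation, demographic
#' characteristics, economic environment, labor market characteristics and
#' strength of health policies.
#'
#' @export
MODERATOR_DIMENSIONS <- c("globalization", "demographic", "economic",
                          "labor", "health_policy")

PANEL_STRATA <- c("male", "female", "overall")

#' Default column-name schema for panel CSV files
#'
#' Maps the internal field names to the column names used in panel CSV files.
#'
#' @param country,year,stratum,prevalence,gdppc column names in the file.
#' @return Named character vector.
#' @export
panel_schema <- function(country = "country", year = "year",
                         stratum = "stratum", prevalence = "prevalence_pct",
                         gdppc = "gdppc") {
  c(country = country, year = year, stratum = stratum,
    prevalence = prevalence, gdppc = gdppc)
}

#' Validate a country-year obesity/income panel
#'
#' Checks a long-format data frame of country-year observations against the
#' panel contract: unique (country, year, stratum) keys, prevalence strictly
#' inside (0, 100) percent, strictly positive GDP per capita (both are
#' log-transformed downstream), known stratum labels, and at least three
#' distinct years per country-stratum (the minimum for a two-parameter
#' per-country regression with a residual). Rows violating row-level
#' invariants are removed and reported; duplicate keys are an error.
#'
#' @param df data frame with columns `country`, `year`, `stratum`,
#'   `prevalence`, `gdppc`.
#' @return A validated panel data frame of class `cyp_panel`, with the removed
#'   rows (and reasons) in attribute `"rejected"`.
#' @export
validate_panel <- function(df) {
  required <- c("country", "year", "stratum", "prevalence", "gdppc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$country <- as.character(df$country)
  df$stratum <- as.character(df$stratum)
  df$year <- as.integer(df$year)

  key <- paste(df$country, df$year, df$stratum, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (country, year, stratum) keys: ",
         paste(gsub("\r", "/", utils::head(dup, 10L)), collapse = ", "),
         if (length(dup) > 10L) " ..." else "", call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  bad(!df$stratum %in% PANEL_STRATA, "unknown stratum")
  bad(df$prevalence <= 0, "non-positive prevalence")
  bad(df$prevalence >= 100, "prevalence at or above 100")
  bad(df$gdppc <= 0, "non-positive gdppc")
  bad(is.na(df$year), "missing year")

  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  out <- df[keep, , drop = FALSE]

  # country-stratum cells too short for a per-country regression
  if (nrow(out) > 0) {
    cell <- paste(out$country, out$stratum, sep = "\r")
    n_years <- tapply(out$year, cell, function(y) length(unique(y)))
    short <- names(n_years)[n_years < 3L]
    if (length(short) > 0) {
      drop <- cell %in% short
      extra <- out[drop, , drop = FALSE]
      extra$reason <- "fewer than 3 distinct years for country-stratum"
      rejected <- rbind(rejected, extra)
      out <- out[!drop, , drop = FALSE]
    }
  }

  rownames(out) <- NULL
  rownames(rejected) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("cyp_panel", "data.frame")
  out
}

#' Read a country-year panel from CSV
#'
#' @param path path to a CSV file with a header row (UTF-8, `.` decimal
#'   separator). Lines starting with `#` are ignored.
#' @param schema column-name map from [panel_schema()].
#' @return A validated panel (see [validate_panel()]); rejected rows are
#'   reported with a warning and kept in attribute `"rejected"`.
#' @export
read_panel <- function(path, schema = panel_schema()) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("panel file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(country = raw[[schema[["country"]]]],
                   year = raw[[schema[["year"]]]],
                   stratum = raw[[schema[["stratum"]]]],
                   prevalence = raw[[schema[["prevalence"]]]],
                   gdppc = raw[[schema[["gdppc"]]]],
                   stringsAsFactors = FALSE)
  panel <- validate_panel(df)
  rej <- attr(panel, "rejected")
  if (nrow(rej) > 0) {
    warning(nrow(rej), " row(s) rejected during panel validation; ",
            "see attr(panel, 'rejected')", call. = FALSE)
  }
  panel
}

#' Write a country-year panel to CSV
#'
#' Values are written with full double precision (15 significant digits) so a
#' write-then-read round trip reproduces the panel.
#'
#' @param panel validated panel.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(country = panel$country, year = panel$year,
                    stratum = panel$stratum,
                    prevalence_pct = format(panel$prevalence, digits = 15,
                                            trim = TRUE, scientific = FALSE),
                    gdppc = format(panel$gdppc, digits = 15, trim = TRUE,
                                   scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a moderator table from CSV
#'
#' Long format: one row per (country, variable) with the variable's dimension
#' tag, dummy flag and value.
#'
#' @param path CSV with columns `country`, `variable`, `dimension`,
#'   `is_dummy`, `value`.
#' @return Data frame of class `moderator_table`.
#' @export
read_moderators <- function(path) {
  if (!file.exists(path)) stop("moderator file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  as_moderator_table(df)
}

#' Construct a moderator table from a data frame
#'
#' @param df data frame with columns `country`, `variable`, `dimension`,
#'   `is_dummy`, `value`.
#' @return Data frame of class `moderator_table`.
#' @export
as_moderator_table <- function(df) {
  required <- c("country", "variable", "dimension", "is_dummy", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("moderator table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$country <- as.character(df$country)
  df$variable <- as.character(df$variable)
  df$dimension <- as.character(df$dimension)
  df$is_dummy <- as.logical(df$is_dummy)
  bad_dim <- setdiff(unique(df$dimension), MODERATOR_DIMENSIONS)
  if (length(bad_dim) > 0) {
    stop("unknown moderator dimension(s): ",
         paste(bad_dim, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$country, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (country, variable) entries in moderator table",
         call. = FALSE)
  }
  # a variable must carry one dimension and one dummy flag
  per_var <- unique(df[c("variable", "dimension", "is_dummy")])
  if (anyDuplicated(per_var$variable)) {
    stop("moderator variable tagged with conflicting dimension/dummy flags",
         call. = FALSE)
  }
  dummies <- df$value[df$is_dummy]
  if (length(dummies) > 0 && !all(dummies %in% c(0, 1))) {
    stop("dummy moderator values must be 0 or 1", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("moderator_table", "data.frame")
  df
}

#' Write a moderator table to CSV
#' @param mods moderator table.
#' @param path output path.
#' @export
write_moderators <- function(mods, path) {
  out <- as.data.frame(mods)
  out$value <- format(out$value, digits = 15, trim = TRUE, scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize moderator covariates
#'
#' Z-scores every non-dummy covariate across countries (sample standard
#' deviation, denominator n-1) so their relative moderating effects are
#' comparable; dummy covariates pass through unchanged. Idempotent up to
#' numerical tolerance.
#'
#' @param mods moderator table (long format).
#' @return Standardized moderator table.
#' @export
standardize_moderators <- function(mods) {
  mods <- as_moderator_table(mods)
  for (v in unique(mods$variable)) {
    idx <- mods$variable == v
    if (mods$is_dummy[idx][1]) next
    x <- mods$value[idx]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate covariate (zero variance): ", v, call. = FALSE)
    }
    mods$value[idx] <- (x - mean(x)) / s
  }
  mods
}

#' Country-by-variable moderator design matrix
#'
#' Pivots a long moderator table to a numeric matrix with one row per country
#' and one column per variable, optionally prepending an intercept column.
#'
#' @param mods moderator table.
#' @param countries row order; default: sorted unique countries in `mods`.
#'   Every requested country must be fully covered.
#' @param intercept prepend a column of ones named `"(Intercept)"`.
#' @return Numeric matrix with attributes `"dimension"` and `"is_dummy"`
#'   (per variable column).
#' @export
moderator_matrix <- function(mods, countries = NULL, intercept = FALSE) {
  mods <- as_moderator_table(mods)
  vars <- unique(mods$variable)
  if (is.null(countries)) countries <- sort(unique(mods$country))
  X <- matrix(NA_real_, length(countries), length(vars),
              dimnames = list(countries, vars))
  idx <- cbind(match(mods$country, countries), match(mods$variable, vars))
  ok <- !is.na(idx[, 1])
  X[idx[ok, , drop = FALSE]] <- mods$value[ok]
  if (anyNA(X)) {
    miss <- countries[apply(X, 1, anyNA)]
    stop("moderator table does not cover country(ies): ",
         paste(utils::head(miss, 10L), collapse = ", "), call. = FALSE)
  }
  per_var <- unique(mods[c("variable", "dimension", "is_dummy")])
  dim_tag <- setNames(per_var$dimension, per_var$variable)[vars]
  dum_tag <- setNames(per_var$is_dummy, per_var$variable)[vars]
  if (intercept) {
    X <- cbind("(Intercept)" = 1, X)
    dim_tag <- c("(Intercept)" = NA_character_, dim_tag)
    dum_tag <- c("(Intercept)" = FALSE, dum_tag)
  }
  attr(X, "dimension") <- dim_tag
  attr(X, "is_dummy") <- dum_tag
  X
}

#' Read / write country group classifications
#'
#' Income-group (high / upper_middle / lower_middle / low) and region
#' assignments, one row per country.
#'
#' @param path CSV with columns `country`, `income_group`, `region`.
#' @return Data frame with those columns.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("country", "income_group", "region")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("group file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$country)) {
    stop("country assigned to more than one group", call. = FALSE)
  }
  ok <- df$income_group %in% c("high", "upper_middle", "lower_middle", "low")
  if (!all(ok)) {
    stop("unknown income_group label(s): ",
         paste(unique(df$income_group[!ok]), collapse = ", "), call. = FALSE)
  }
  df[required]
}

#' @rdname read_groups
#' @param groups group table.
#' @export
write_groups <- function(groups, path) {
  write.csv(groups[c("country", "income_group", "region")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write income growth projections
#'
#' Per-country projected annual GDP-per-capita growth (percent) over a
#' forecast horizon, with optional bridge years of actual growth between the
#' panel end and the projection start (flagged by `is_bridge`).
#'
#' @param path CSV with columns `country`, `year`, `growth_pct`, `is_bridge`.
#' @return Data frame of class `income_projections`.
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop("projection file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  as_projections(df)
}

#' Construct an income projection table from a data frame
#' @param df data frame with columns `country`, `year`, `growth_pct`,
#'   `is_bridge`.
#' @return Data frame of class `income_projections`.
#' @export
as_projections <- function(df) {
  required <- c("country", "year", "growth_pct", "is_bridge")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("projection table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$country <- as.character(df$country)
  df$year <- as.integer(df$year)
  df$is_bridge <- as.logical(df$is_bridge)
  if (any(df$growth_pct <= -100)) {
    stop("projected growth must exceed -100%", call. = FALSE)
  }
  df <- df[order(df$country, df$year), ]
  by_country <- split(df$year, df$country)
  gaps <- vapply(by_country, function(y) any(diff(y) != 1L), logical(1))
  if (any(gaps)) {
    stop("projection years not consecutive for country(ies): ",
         paste(names(by_country)[gaps], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("income_projections", "data.frame")
  df
}

#' @rdname read_projections
#' @param projections projection table.
#' @export
write_projections <- function(projections, path) {
  out <- as.data.frame(projections)
  out$growth_pct <- format(out$growth_pct, digits = 15, trim = TRUE,
                           scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compounded annual growth rate
#'
#' CAGR between two endpoint values over `n_intervals` annual intervals,
#' in percent per year: `100 * ((end/start)^(1/n) - 1)`. Scale-invariant in
#' the endpoints.
#'
#' @param start_value,end_value positive endpoint values (vectorized).
#' @param n_intervals number of annual intervals between them (>= 1); for a
#'   1975-to-2014 span this is 39.
#' @return Growth rate(s) in percent per year.
#' @examples
#' compute_cagr(5.41, 17.51, 39)  # ~3.06
#' @export
compute_cagr <- function(start_value, end_value, n_intervals) {
  if (any(start_value <= 0) || any(end_value <= 0)) {
    stop("CAGR endpoints must be positive", call. = FALSE)
  }
  if (any(n_intervals < 1)) {
    stop("n_intervals must be at least 1", call. = FALSE)
  }
  100 * ((end_value / start_value)^(1 / n_intervals) - 1)
}

#' Group-wise prevalence summary for one year
#'
#' Unweighted mean and sample standard deviation of prevalence across the
#' countries of each income group, by stratum, for a given year. A weighted
#' mean is available by supplying per-country weights (e.g. population), but
#' the unweighted country average is the default. Groups represented by a
#' single country get `NA` standard deviation.
#'
#' @param panel validated panel.
#' @param groups group table (see [read_groups()]).
#' @param year calendar year to summarize.
#' @param weights optional named numeric vector of per-country weights.
#' @return Data frame with columns `income_group`, `stratum`, `n_countries`,
#'   `mean_prevalence`, `sd_prevalence`.
#' @export
group_summary <- function(panel, groups, year, weights = NULL) {
  sub <- panel[panel$year == year, , drop = FALSE]
  all_countries <- unique(panel$country)
  missing_year <- setdiff(all_countries, unique(sub$country))
  if (length(missing_year) > 0) {
    warning("year ", year, " absent for country(ies): ",
            paste(utils::head(missing_year, 10L), collapse = ", "),
            if (length(missing_year) > 10L) " ..." else "", call. = FALSE)
  }
  m <- merge(sub, groups[c("country", "income_group")], by = "country")
  if (nrow(m) == 0) stop("no observations for year ", year, call. = FALSE)
  wfun <- function(d) {
    if (is.null(weights)) {
      mu <- mean(d$prevalence)
    } else {
      w <- weights[d$country]
      mu <- sum(w * d$prevalence) / sum(w)
    }
    c(n = nrow(d), mean = mu,
      sd = if (nrow(d) > 1) sd(d$prevalence) else NA_real_)
  }
  cells <- split(m, list(m$income_group, m$stratum), drop = TRUE)
  res <- do.call(rbind, lapply(names(cells), function(nm) {
    st <- wfun(cells[[nm]])
    data.frame(income_group = cells[[nm]]$income_group[1],
               stratum = cells[[nm]]$stratum[1],
               n_countries = unname(st["n"]),
               mean_prevalence = unname(st["mean"]),
               sd_prevalence = unname(st["sd"]),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$income_group, res$stratum), ]
  rownames(res) <- NULL
  res
}
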