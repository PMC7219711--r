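FORM_NAMES <- c("linear", "quadratic", "loglog")

#' Mean absolute percentage error
#'
#' `100 * mean(|predicted - actual| / actual)`, the criterion used to compare
#' candidate functional forms on a common prevalence (percent) scale.
#'
#' @param actual,predicted equal-length numeric vectors; `actual` must be
#'   strictly positive.
#' @return MAPE in percent.
#' @export
compute_mape <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (any(actual <= 0)) stop("actual values must be positive", call. = FALSE)
  100 * mean(abs(predicted - actual) / actual)
}

#' Fit one candidate functional form country-by-country
#'
#' Ordinary least squares of the stated equation per country:
#' \describe{
#'   \item{linear}{`prev = alpha_c + beta_c * gdppc`}
#'   \item{quadratic}{`prev = alpha_c + beta1_c * gdppc + beta2_c * gdppc^2`}
#'   \item{loglog}{`ln(prev) = alpha_c + beta_c * ln(gdppc)`}
#' }
#' GDP per capita is rescaled to thousands for the linear and quadratic
#' forms (the squared column is otherwise catastrophically ill-conditioned);
#' coefficients are reported in those rescaled units. Log-log fitted values
#' are back-transformed with `exp` (no smearing correction) so the MAPE of
#' all three forms is computed on the same original percent scale.
#'
#' @param panel validated panel.
#' @param form one of `"linear"`, `"quadratic"`, `"loglog"`.
#' @param stratum stratum to fit (default `"overall"`).
#' @return Object of class `form_fit`: the form, per-country coefficients,
#'   fitted values on the percent scale, and the overall MAPE.
#' @export
fit_form <- function(panel, form = FORM_NAMES, stratum = "overall") {
  form <- match.arg(form)
  sub <- panel[panel$stratum == stratum, , drop = FALSE]
  if (nrow(sub) == 0) stop("no observations for stratum ", stratum, call. = FALSE)
  n_par <- if (form == "quadratic") 3L else 2L

  countries <- unique(sub$country)
  coefs <- vector("list", length(countries))
  fitted_rows <- vector("list", length(countries))
  skipped <- character(0)
  for (i in seq_along(countries)) {
    d <- sub[sub$country == countries[i], ]
    if (nrow(d) < n_par) {
      skipped <- c(skipped, countries[i])
      next
    }
    g <- d$gdppc / 1000
    if (form == "loglog") {
      Xc <- cbind(1, log(d$gdppc))
      yc <- log(d$prevalence)
    } else if (form == "linear") {
      Xc <- cbind(1, g)
      yc <- d$prevalence
    } else {
      Xc <- cbind(1, g, g^2)
      yc <- d$prevalence
    }
    fit <- stats::lm.fit(Xc, yc)
    pred <- drop(Xc %*% fit$coefficients)
    if (form == "loglog") pred <- exp(pred)
    cf <- fit$coefficients
    coefs[[i]] <- if (form == "quadratic") {
      data.frame(country = countries[i], alpha = cf[1], beta1 = cf[2],
                 beta2 = cf[3], stringsAsFactors = FALSE)
    } else {
      data.frame(country = countries[i], alpha = cf[1], beta = cf[2],
                 stringsAsFactors = FALSE)
    }
    fitted_rows[[i]] <- data.frame(country = d$country, year = d$year,
                                   actual = d$prevalence, fitted = pred,
                                   stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("excluded country(ies) with fewer observations than parameters: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  fitted <- do.call(rbind, fitted_rows)
  if (is.null(fitted)) stop("no country could be fitted", call. = FALSE)
  if (any(!is.finite(fitted$fitted))) {
    stop("non-finite fitted values in ", form, " fit", call. = FALSE)
  }
  structure(list(form = form, stratum = stratum,
                 coefficients = do.call(rbind, coefs),
                 fitted = fitted,
                 mape = compute_mape(fitted$actual, fitted$fitted)),
            class = "form_fit")
}

#' Select the best-fitting functional form by MAPE
#'
#' @param fits list of `form_fit` objects over the same panel/stratum.
#' @param tie_tol ties in MAPE closer than this are flagged; the
#'   first-listed form wins.
#' @return List with `form` (the winner), `mape_table` (form, mape) and
#'   `tie` flag.
#' @export
select_form <- function(fits, tie_tol = 1e-9) {
  if (inherits(fits, "form_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  mapes <- vapply(fits, function(f) f$mape, numeric(1))
  forms <- vapply(fits, function(f) f$form, character(1))
  best <- which.min(mapes)
  tie <- sum(mapes - mapes[best] < tie_tol) > 1
  if (tie) {
    warning("MAPE tie within ", tie_tol, "; returning first-listed form",
            call. = FALSE)
  }
  list(form = forms[best],
       mape_table = data.frame(form = forms, mape = mapes,
                               stringsAsFactors = FALSE),
       tie = tie)
}

#' Run the three-way functional-form contest
#'
#' Fits linear, quadratic and log-log forms and selects the winner by MAPE.
#'
#' @inheritParams fit_form
#' @return As [select_form()], with the fits attached as `fits`.
#' @export
form_contest <- function(panel, stratum = "overall") {
  fits <- lapply(FORM_NAMES, function(f) fit_form(panel, f, stratum))
  res <- select_form(fits)
  res$fits <- fits
  res
}
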