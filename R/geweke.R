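#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of an MCMC chain (first
#' `first_frac` of the draws) with a late segment (last `last_frac`),
#' standardized by spectral-density-at-zero estimates of each segment mean's
#' variance: `Z = (mean_first - mean_last) / sqrt(S1/n1 + S2/n2)`. Under
#' convergence Z is approximately standard normal; `|Z| < 1.96` is the
#' conventional pass criterion.
#'
#' The spectral density at zero is estimated by a Bartlett lag-windowed
#' autocovariance sum with window length `ceiling(4 * (n_segment/100)^0.25)`.
#'
#' @param chain numeric vector of draws (length >= 200, not constant).
#' @param first_frac,last_frac segment fractions (conventional 0.1 and 0.5).
#' @return The Z score (numeric scalar).
#' @export
geweke_diagnostic <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 200) stop("chain must have at least 200 draws", call. = FALSE)
  if (first_frac + last_frac > 1) {
    stop("segment fractions must not overlap", call. = FALSE)
  }
  if (var(chain) == 0) stop("degenerate (constant) chain", call. = FALSE)
  n1 <- floor(first_frac * n)
  n2 <- floor(last_frac * n)
  seg1 <- chain[seq_len(n1)]
  seg2 <- chain[seq.int(n - n2 + 1L, n)]
  v1 <- spectral0(seg1) / n1
  v2 <- spectral0(seg2) / n2
  (mean(seg1) - mean(seg2)) / sqrt(v1 + v2)
}

# spectral density at frequency zero via Bartlett-windowed autocovariances
spectral0 <- function(x) {
  n <- length(x)
  L <- ceiling(4 * (n / 100)^0.25)
  L <- min(L, n - 1L)
  xc <- x - mean(x)
  g0 <- sum(xc^2) / n
  s <- g0
  for (k in seq_len(L)) {
    gk <- sum(xc[seq_len(n - k)] * xc[seq.int(k + 1L, n)]) / n
    s <- s + 2 * (1 - k / (L + 1)) * gk
  }
  if (s <= 0) s <- g0  # lag-window estimates can go negative; fall back
  s
}

#' Geweke diagnostics for all second-stage coefficient chains
#'
#' @param draws `posterior_draws` object.
#' @param threshold pass criterion on `|Z|`.
#' @return Data frame with columns `equation`, `variable`, `z`, `converged`.
#' @export
geweke_table <- function(draws, threshold = 1.96) {
  stopifnot(inherits(draws, "posterior_draws"))
  res <- do.call(rbind, lapply(c("alpha", "beta"), function(eq) {
    do.call(rbind, lapply(seq_along(draws$coef_names), function(j) {
      z <- geweke_diagnostic(draws$Delta[, j, eq])
      data.frame(equation = eq, variable = draws$coef_names[j], z = z,
                 stringsAsFactors = FALSE)
    }))
  }))
  res$converged <- abs(res$z) < threshold
  rownames(res) <- NULL
  res
}
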