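#' Pairwise correlation screen for moderator candidates
#'
#' Computes pairwise Pearson correlations between moderator variables and
#' marks pairs whose `|r|` exceeds the threshold as mutually exclusive for
#' selection (only one of such a pair may enter the model).
#'
#' @param mods moderator table (standardized).
#' @param threshold absolute-correlation threshold (default 0.7).
#' @return List of class `correlation_screen`: `pairs` (var1, var2, r,
#'   excluded) and the threshold.
#' @export
correlation_screen <- function(mods, threshold = 0.7) {
  X <- moderator_matrix(mods)
  vars <- colnames(X)
  R <- cor(X)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                      r = R[idx], stringsAsFactors = FALSE)
  pairs$excluded <- abs(pairs$r) > threshold
  structure(list(pairs = pairs, threshold = threshold),
            class = "correlation_screen")
}

# helper: variables barred by correlation with an already-selected set
barred_with <- function(screen_pairs, selected) {
  ex <- screen_pairs[screen_pairs$excluded, , drop = FALSE]
  unique(c(ex$var2[ex$var1 %in% selected], ex$var1[ex$var2 %in% selected]))
}

#' Iterative forward selection of macro-environmental moderators
#'
#' Two-phase forward selection of the second-stage regression, scored by
#' classical AIC/BIC on ordinary least squares fits of the per-country
#' elasticities on candidate moderators. Phase 1 adds one variable at a time,
#' always choosing among dimensions not yet represented, until every one of
#' the five dimensions has contributed a variable; within a step the
#' best-BIC candidate whose coefficient is significant at the 5% level is
#' taken (when AIC and BIC disagree, BIC wins; if no candidate is
#' significant, the best-BIC candidate is taken with a warning). Phase 2
#' continues over all remaining admissible candidates and stops when no
#' addition improves BIC by at least `min_improve` with a significant
#' coefficient (the default margin of 2 is the conventional
#' "positive evidence" threshold for BIC differences). Candidates whose
#' absolute correlation with an already-selected variable exceeds the screen
#' threshold are inadmissible throughout.
#'
#' @param response per-country elasticity values: a named numeric vector
#'   (names are country ids) or a data frame with columns `country` and
#'   `beta`.
#' @param mods standardized moderator table covering every response country.
#' @param threshold correlation-screen threshold (see
#'   [correlation_screen()]).
#' @param alpha_level nominal significance level for the coefficient test.
#' @param min_improve minimum BIC improvement for a phase-2 addition.
#' @param alpha_response optional per-country intercepts; when supplied the
#'   intercept equation is refit with the final selected set.
#' @return Object of class `selection_state`: `selected` (ordered),
#'   `trace` (every candidate evaluation), `beta_model`, `alpha_model`
#'   (or NULL) and the screen.
#' @export
forward_select <- function(response, mods, threshold = 0.7,
                           alpha_level = 0.05, min_improve = 2,
                           alpha_response = NULL) {
  if (is.data.frame(response)) {
    y <- setNames(response$beta, response$country)
  } else {
    y <- response
  }
  if (is.null(names(y))) stop("response must be named by country", call. = FALSE)
  X <- moderator_matrix(mods, countries = names(y))
  dims <- attr(X, "dimension")
  screen <- correlation_screen(mods, threshold)

  fit_with <- function(vars) {
    df <- data.frame(y = y, X[, vars, drop = FALSE], check.names = FALSE)
    lm(y ~ ., data = df)
  }
  crit <- function(model) c(aic = AIC(model), bic = BIC(model))

  eval_candidates <- function(selected, candidates, phase, step) {
    do.call(rbind, lapply(candidates, function(v) {
      m <- fit_with(c(selected, v))
      sm <- summary(m)$coefficients
      tv <- sm[rownames(sm) == paste0("`", v, "`") | rownames(sm) == v, 3]
      if (length(tv) == 0) tv <- NA_real_
      cr <- crit(m)
      data.frame(phase = phase, step = step, candidate = v,
                 dimension = unname(dims[v]), aic = cr["aic"],
                 bic = cr["bic"], tstat = unname(tv),
                 selected = FALSE, stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
  }

  selected <- character(0)
  dims_done <- character(0)
  trace <- list()
  step <- 0L
  t_crit <- function(model) qt(1 - alpha_level / 2, df = model$df.residual)

  # phase 1: ensure one variable per dimension
  all_dims <- intersect(MODERATOR_DIMENSIONS, unique(dims))
  while (length(dims_done) < length(all_dims)) {
    step <- step + 1L
    barred <- barred_with(screen$pairs, selected)
    candidates <- colnames(X)[!dims[colnames(X)] %in% dims_done &
                              !colnames(X) %in% c(selected, barred)]
    if (length(candidates) == 0) {
      stop("no admissible candidate for dimension(s): ",
           paste(setdiff(all_dims, dims_done), collapse = ", "),
           call. = FALSE)
    }
    ev <- eval_candidates(selected, candidates, 1L, step)
    ord <- order(ev$bic)
    crit_t <- qt(1 - alpha_level / 2,
                 df = length(y) - length(selected) - 2L)
    sig <- which(abs(ev$tstat[ord]) > crit_t)
    pick <- if (length(sig) > 0) ord[sig[1]] else {
      warning("phase 1 step ", step,
              ": no significant candidate; taking best-BIC candidate ",
              ev$candidate[ord[1]], call. = FALSE)
      ord[1]
    }
    ev$selected[pick] <- TRUE
    trace[[length(trace) + 1L]] <- ev
    selected <- c(selected, ev$candidate[pick])
    dims_done <- c(dims_done, ev$dimension[pick])
  }

  # phase 2: free forward steps until BIC stops improving
  current_bic <- BIC(fit_with(selected))
  repeat {
    barred <- barred_with(screen$pairs, selected)
    candidates <- setdiff(colnames(X), c(selected, barred))
    if (length(candidates) == 0) break
    step <- step + 1L
    ev <- eval_candidates(selected, candidates, 2L, step)
    best <- which.min(ev$bic)
    crit_t <- qt(1 - alpha_level / 2,
                 df = length(y) - length(selected) - 2L)
    ok <- (current_bic - ev$bic[best]) >= min_improve &&
      is.finite(ev$tstat[best]) && abs(ev$tstat[best]) > crit_t
    if (ok) ev$selected[best] <- TRUE
    trace[[length(trace) + 1L]] <- ev
    if (!ok) break
    selected <- c(selected, ev$candidate[best])
    current_bic <- ev$bic[best]
  }

  beta_model <- fit_with(selected)
  alpha_model <- NULL
  if (!is.null(alpha_response)) {
    ya <- if (is.data.frame(alpha_response)) {
      setNames(alpha_response$alpha, alpha_response$country)
    } else alpha_response
    dfa <- data.frame(y = ya[names(y)], X[, selected, drop = FALSE],
                      check.names = FALSE)
    alpha_model <- lm(y ~ ., data = dfa)
  }
  structure(list(selected = selected,
                 trace = do.call(rbind, trace),
                 beta_model = beta_model, alpha_model = alpha_model,
                 screen = screen, min_improve = min_improve,
                 alpha_level = alpha_level),
            class = "selection_state")
}
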