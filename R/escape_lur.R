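# Supervised forward selection in the ESCAPE tradition: candidates must be
# non-null for >10% of sites, each entering predictor must carry its
# a-priori sign and must not flip the sign of any predictor already in the
# model, each accepted step must raise R-squared by at least 1 percentage
# point, and the final model is pruned on VIF (< 3), coefficient p-values
# (< 0.1) and screened for influential sites (Cook's D >= 1 flagged, never
# auto-removed).

#' Screen candidate predictors
#'
#' Retains columns whose fraction of non-zero values exceeds the threshold
#' (structural zeros, not missingness: buffer predictors have no missing
#' cells) and drops constant columns unconditionally.
#'
#' @param pm a `predictor_matrix`.
#' @param threshold minimum fraction of non-zero values (strict `>`).
#' @return character vector of retained column names.
#' @export
screen_candidates <- function(pm, threshold = 0.10) {
  X <- pm$values
  if (is.null(X) || nrow(X) == 0L) abort_lur("lur_screen_error", "empty predictor matrix")
  nonzero <- colMeans(X != 0)
  constant <- apply(X, 2, function(col) max(col) == min(col))
  colnames(X)[nonzero > threshold & !constant]
}

sign_of <- function(s) ifelse(s == "+", 1, -1)

ols_fit <- function(y, X, terms) {
  df <- data.frame(y = y, X[, terms, drop = FALSE], check.names = FALSE)
  stats::lm(y ~ ., data = df)
}

r_squared <- function(fit, adjusted = FALSE) {
  s <- summary(fit)
  if (adjusted) s$adj.r.squared else s$r.squared
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j regresses column j on the other
#' columns (with intercept). A single column has VIF 1 by definition;
#' perfect collinearity yields `Inf`.
#'
#' @param X numeric matrix restricted to the model terms.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 2L) {
    return(stats::setNames(rep(1, k), colnames(X)))
  }
  out <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

term_table <- function(fit, pm, terms, inc_r2) {
  cf <- summary(fit)$coefficients
  v <- vif(pm$values[, terms, drop = FALSE])
  data.frame(
    name = terms,
    coefficient = unname(cf[terms, 1]),
    expected_sign = vapply(terms, function(t) pm$specs[[t]]$expected_sign, character(1)),
    p_value = unname(cf[terms, 4]),
    vif = unname(v[terms]),
    inc_r2 = inc_r2,
    stringsAsFactors = FALSE
  )
}

new_lur_fit <- function(pm, y, terms, inc_r2, trace, prune_log = NULL,
                        pollutant = NA_character_, season = NA_character_,
                        adjusted_r2 = FALSE) {
  if (length(terms) == 0L) {
    fit <- stats::lm(y ~ 1)
    tt <- data.frame(
      name = character(0), coefficient = numeric(0), expected_sign = character(0),
      p_value = numeric(0), vif = numeric(0), inc_r2 = numeric(0)
    )
    r2 <- 0
  } else {
    fit <- ols_fit(y, pm$values, terms)
    tt <- term_table(fit, pm, terms, inc_r2)
    r2 <- r_squared(fit, adjusted_r2)
  }
  cd <- stats::cooks.distance(fit)
  structure(
    list(
      pollutant = pollutant, season = season,
      intercept = unname(stats::coef(fit)[1]),
      terms = tt, r_squared = r2, n_sites = length(y),
      max_cooks_d = max(cd),
      influential_sites = pm$site_id[cd >= 1],
      specs = pm$specs[terms],
      fitted = unname(stats::fitted(fit)), residuals = unname(stats::residuals(fit)),
      site_id = pm$site_id,
      selection_trace = trace, prune_log = prune_log,
      adjusted_r2 = adjusted_r2
    ),
    class = "lur_fit"
  )
}

#' Supervised forward selection with sign vetoes
#'
#' Starting from the intercept-only model, each round fits OLS with every
#' remaining candidate added; a candidate is eligible only if its own
#' coefficient carries its expected sign and every previously accepted term
#' keeps its expected sign. The eligible candidate with the largest gain in
#' R-squared enters if the gain is at least `min_gain` (1% by default),
#' otherwise selection stops. Ties are broken by lexicographic predictor
#' name; the full per-step trace (gains, veto reasons) is recorded.
#'
#' @param response numeric vector of adjusted site means, aligned to
#'   `pm$values` rows.
#' @param pm a `predictor_matrix`.
#' @param candidates candidate column names; defaults to
#'   [screen_candidates()] of `pm`. An empty candidate set yields an
#'   intercept-only fit, not an error.
#' @param min_gain minimum R-squared increase per accepted step.
#' @param adjusted_r2 use adjusted instead of plain R-squared throughout.
#' @param pollutant,season labels carried into the fit.
#' @return a `lur_fit`.
#' @export
forward_select <- function(response, pm, candidates = NULL, min_gain = 0.01,
                           adjusted_r2 = FALSE,
                           pollutant = NA_character_, season = NA_character_) {
  stopifnot(inherits(pm, "predictor_matrix"))
  y <- as.numeric(response)
  if (length(y) != nrow(pm$values)) {
    abort_lur("lur_fit_error", "response length %d != %d sites", length(y), nrow(pm$values))
  }
  candidates <- sort(candidates %||% screen_candidates(pm))
  selected <- character(0)
  inc_r2 <- numeric(0)
  r2_cur <- 0
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(selected) + 2L >= length(y)) break
    best <- NULL
    best_gain <- -Inf
    for (cand in setdiff(candidates, selected)) {
      terms <- c(selected, cand)
      fit <- ols_fit(y, pm$values, terms)
      cf <- stats::coef(fit)[-1]
      r2 <- r_squared(fit, adjusted_r2)
      gain <- r2 - r2_cur
      reason <- ""
      eligible <- TRUE
      if (anyNA(cf)) {
        eligible <- FALSE
        reason <- "collinear"
      } else {
        want <- vapply(terms, function(t) sign_of(pm$specs[[t]]$expected_sign), numeric(1))
        bad <- sign(cf) != want
        if (bad[[cand]]) {
          eligible <- FALSE
          reason <- "wrong sign"
        } else if (any(bad)) {
          eligible <- FALSE
          reason <- paste("flips sign of", paste(terms[bad], collapse = ","))
        }
      }
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, candidate = cand, r2 = r2, gain = gain,
        eligible = eligible, reason = reason, accepted = FALSE,
        stringsAsFactors = FALSE
      )
      if (eligible && gain > best_gain + 1e-15) {
        best <- cand
        best_gain <- gain
      }
    }
    if (is.null(best) || best_gain < min_gain - 1e-12) break
    selected <- c(selected, best)
    inc_r2 <- c(inc_r2, best_gain)
    r2_cur <- r2_cur + best_gain
    for (i in seq_along(trace)) {
      if (trace[[i]]$step == step && trace[[i]]$candidate == best) trace[[i]]$accepted <- TRUE
    }
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else data.frame(
    step = integer(0), candidate = character(0), r2 = numeric(0), gain = numeric(0),
    eligible = logical(0), reason = character(0), accepted = logical(0)
  )
  fit <- new_lur_fit(pm, y, selected, inc_r2, trace_df,
    pollutant = pollutant, season = season, adjusted_r2 = adjusted_r2
  )
  nested_radius_note(fit)
  if (length(selected) > length(y) / 10) {
    warn_lur("lur_fit_warning", "%d terms for %d sites (> n/10)", length(selected), length(y))
  }
  fit
}

nested_radius_note <- function(fit) {
  sp <- fit$specs
  if (length(sp) < 2L) return(invisible(NULL))
  buffered <- vapply(sp, function(s) !is.null(s$buffer_radius), logical(1))
  sp <- sp[buffered]
  if (length(sp) < 2L) return(invisible(NULL))
  key <- vapply(sp, function(s) paste(s$source_category, s$aggregation), character(1))
  for (k in unique(key[duplicated(key)])) {
    radii <- vapply(sp[key == k], `[[`, numeric(1), "buffer_radius")
    if (length(unique(radii)) > 1L) {
      message(
        "note: nested buffer radii of the same source co-occur in the model: ",
        paste(names(sp)[key == k], collapse = ", ")
      )
    }
  }
  invisible(NULL)
}

#' Prune a model on VIF and p-value; flag influential sites
#'
#' Iteratively drops the highest-VIF term while any VIF >= 3, then the
#' highest-p term while any p >= 0.1 (refitting after each drop, VIF before
#' p so collinearity cannot distort the significance decisions), then
#' computes Cook's distance over sites and flags (never removes) sites with
#' D >= 1. If pruning empties the model, the intercept-only fit is returned
#' with an explanatory prune log.
#'
#' @param fit a `lur_fit` from [forward_select()].
#' @param pm the `predictor_matrix` used to build it.
#' @param response the response vector used to build it.
#' @param max_vif,max_p thresholds (defaults 3 and 0.1).
#' @return a pruned `lur_fit` satisfying all invariants.
#' @export
prune_diagnostics <- function(fit, pm, response, max_vif = 3, max_p = 0.1) {
  stopifnot(inherits(fit, "lur_fit"))
  y <- as.numeric(response)
  terms <- fit$terms$name
  inc <- stats::setNames(fit$terms$inc_r2, terms)
  log <- list()
  repeat {
    if (length(terms) == 0L) break
    v <- vif(pm$values[, terms, drop = FALSE])
    if (max(v) < max_vif) break
    drop <- names(which.max(v))
    log[[length(log) + 1L]] <- sprintf("dropped %s (VIF %.2f >= %g)", drop, max(v), max_vif)
    terms <- setdiff(terms, drop)
  }
  repeat {
    if (length(terms) == 0L) break
    f <- ols_fit(y, pm$values, terms)
    p <- summary(f)$coefficients[terms, 4]
    if (max(p) < max_p) break
    drop <- terms[which.max(p)]
    log[[length(log) + 1L]] <- sprintf("dropped %s (p %.3f >= %g)", drop, max(p), max_p)
    terms <- setdiff(terms, drop)
  }
  if (length(terms) == 0L && nrow(fit$terms) > 0L) {
    log[[length(log) + 1L]] <- "pruning emptied the model; returning intercept-only fit"
  }
  out <- new_lur_fit(pm, y, terms, unname(inc[terms]), fit$selection_trace,
    prune_log = unlist(log),
    pollutant = fit$pollutant, season = fit$season, adjusted_r2 = fit$adjusted_r2
  )
  check_lur_fit(out, max_vif = max_vif, max_p = max_p)
  out
}

# Invariants asserted on every final fit: signs match expectations,
# p < 0.1, VIF < 3, R2 in [0, 1], accepted increments >= 1%.
check_lur_fit <- function(fit, max_vif = 3, max_p = 0.1, min_gain = 0.01) {
  tt <- fit$terms
  if (nrow(tt) > 0L) {
    if (any(sign(tt$coefficient) != sign_of(tt$expected_sign))) {
      abort_lur("lur_invariant_error", "a term's coefficient contradicts its expected sign")
    }
    if (any(tt$p_value >= max_p)) abort_lur("lur_invariant_error", "a term has p >= %g", max_p)
    if (any(tt$vif >= max_vif)) abort_lur("lur_invariant_error", "a term has VIF >= %g", max_vif)
    if (any(tt$inc_r2 < min_gain - 1e-12)) {
      abort_lur("lur_invariant_error", "an accepted step gained < %g R2", min_gain)
    }
  }
  if (fit$r_squared < -1e-12 || fit$r_squared > 1 + 1e-12) {
    abort_lur("lur_invariant_error", "R2 outside [0, 1]")
  }
  invisible(TRUE)
}

#' Screen, select and prune in one call
#'
#' @inheritParams forward_select
#' @inheritParams prune_diagnostics
#' @param screen_threshold non-null fraction for [screen_candidates()].
#' @return a `lur_fit`.
#' @export
fit_lur <- function(response, pm, screen_threshold = 0.10, min_gain = 0.01,
                    max_vif = 3, max_p = 0.1, adjusted_r2 = FALSE,
                    pollutant = NA_character_, season = NA_character_) {
  cands <- screen_candidates(pm, screen_threshold)
  fit <- forward_select(response, pm, cands,
    min_gain = min_gain, adjusted_r2 = adjusted_r2,
    pollutant = pollutant, season = season
  )
  prune_diagnostics(fit, pm, response, max_vif = max_vif, max_p = max_p)
}

#' @export
print.lur_fit <- function(x, ...) {
  cat(sprintf(
    "<lur_fit> %s / %s: R2 = %.3f, N = %d, max Cook's D = %.3f\n",
    x$pollutant, x$season, x$r_squared, x$n_sites, x$max_cooks_d
  ))
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  if (nrow(x$terms) > 0L) {
    print(x$terms, row.names = FALSE, digits = 4)
  } else {
    cat("  (intercept-only model)\n")
  }
  invisible(x)
}

#' Human-readable one-line model summary
#'
#' Mirrors the customary LUR results-table layout: predictor list joined by
#' `+`, R2, and N.
#'
#' @param object a `lur_fit`.
#' @param ... unused.
#' @return data frame with `pollutant, season, predictors, r2, n`.
#' @export
summary.lur_fit <- function(object, ...) {
  data.frame(
    pollutant = object$pollutant, season = object$season,
    predictors = if (nrow(object$terms)) paste(object$terms$name, collapse = " + ") else "(intercept only)",
    r2 = object$r_squared, n = object$n_sites, stringsAsFactors = FALSE
  )
}

lur_fit_to_list <- function(fit) {
  list(
    pollutant = fit$pollutant, season = fit$season,
    intercept = fit$intercept,
    terms = if (nrow(fit$terms)) fit$terms else list(),
    r_squared = fit$r_squared, n_sites = fit$n_sites,
    max_cooks_d = fit$max_cooks_d, influential_sites = fit$influential_sites,
    specs = lapply(fit$specs, spec_to_list),
    validation = fit$validation %||% NULL,
    prune_log = fit$prune_log %||% character(0),
    selection_trace = fit$selection_trace
  )
}

#' Write a fitted model (and its trace) as JSON
#'
#' @param fit a `lur_fit`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_lur_json <- function(fit, path) {
  jsonlite::write_json(lur_fit_to_list(fit), path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' Restores what [predict_points()] and [predict_grid()] need (intercept,
#' coefficients, specs); trace and diagnostics are restored as data.
#'
#' @param path JSON path written by [write_lur_json()].
#' @return a `lur_fit` (without fitted/residual vectors).
#' @export
read_lur_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  terms <- if (length(x$terms)) as.data.frame(x$terms) else data.frame(
    name = character(0), coefficient = numeric(0), expected_sign = character(0),
    p_value = numeric(0), vif = numeric(0), inc_r2 = numeric(0)
  )
  specs <- lapply(x$specs, function(m) {
    predictor_spec(m$name, m$source_category, m$aggregation,
      m$buffer_radius %||% NULL, m$expected_sign,
      allow_any_radius = TRUE
    )
  })
  structure(
    list(
      pollutant = x$pollutant, season = x$season, intercept = x$intercept,
      terms = terms, r_squared = x$r_squared, n_sites = x$n_sites,
      max_cooks_d = x$max_cooks_d,
      influential_sites = x$influential_sites,
      specs = stats::setNames(specs, vapply(specs, `[[`, character(1), "name")),
      selection_trace = x$selection_trace, prune_log = x$prune_log,
      validation = x$validation
    ),
    class = "lur_fit"
  )
}
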