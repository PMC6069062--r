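# Model validation: leave-one-out cross-validation with the term set
# frozen (coefficients refit on n-1 sites, selection never re-run), RMSE
# and normalized mean bias, and Moran's I on residuals under
# row-standardized inverse-distance weights with permutation inference.

#' Leave-one-out cross-validation of a fitted LUR model
#'
#' For each site, the coefficients of the fit's (frozen) term set are
#' re-estimated on the other n-1 sites and the held-out site is predicted.
#' The validation R-squared is, by default, the squared Pearson correlation
#' between observed and predicted values across sites (the customary LUR
#' convention); `r2_method = "ss"` gives 1 - SSE/SST instead.
#'
#' @param fit a `lur_fit`.
#' @param pm the `predictor_matrix` it was fit on.
#' @param response the observed response vector.
#' @param r2_method `"pearson"` (default) or `"ss"`.
#' @return list `predictions, loocv_r2, loocv_rmse, loocv_nmb`.
#' @export
loocv <- function(fit, pm, response, r2_method = c("pearson", "ss")) {
  r2_method <- match.arg(r2_method)
  y <- as.numeric(response)
  terms <- fit$terms$name
  n <- length(y)
  if (n < length(terms) + 2L) {
    abort_lur("lur_validation_error", "need at least terms + 2 sites for LOOCV")
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    if (length(terms) == 0L) {
      preds[i] <- mean(y[-i])
      next
    }
    Xtr <- pm$values[-i, terms, drop = FALSE]
    f <- stats::lm.fit(cbind(`(Intercept)` = 1, Xtr), y[-i])
    if (anyNA(f$coefficients)) {
      abort_lur("lur_validation_error", "LOOCV refit is rank-deficient on fold %d (site %s)", i, pm$site_id[i])
    }
    preds[i] <- sum(c(1, pm$values[i, terms]) * f$coefficients)
  }
  r2 <- if (r2_method == "pearson") {
    stats::cor(y, preds)^2
  } else {
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  }
  em <- error_metrics(y, preds)
  list(predictions = preds, loocv_r2 = r2, loocv_rmse = em$rmse, loocv_nmb = em$nmb)
}

#' RMSE and normalized mean bias
#'
#' `rmse = sqrt(mean((pred - obs)^2))`;
#' `nmb = sum(pred - obs) / sum(obs)`. NMB is reported as `NA` (undefined)
#' when the observations sum to zero.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return list `rmse, nmb`.
#' @export
error_metrics <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    abort_lur("lur_validation_error", "observed and predicted must be equal-length and non-empty")
  }
  rmse <- sqrt(mean((predicted - observed)^2))
  nmb <- if (sum(observed) == 0) NA_real_ else sum(predicted - observed) / sum(observed)
  list(rmse = rmse, nmb = nmb)
}

# Row-standardized inverse-distance spatial weights with zero diagonal.
inverse_distance_weights <- function(coords, floor = 1) {
  d <- as.matrix(stats::dist(coords))
  w <- 1 / pmax(d, floor)
  diag(w) <- 0
  w / rowSums(w)
}

#' Moran's I on residuals with permutation inference
#'
#' I = (n / sum(W)) * (z' W z) / (z' z) with z the centred residuals and W
#' row-standardized inverse-distance weights (zero diagonal; distances
#' floored at `floor` metres so coincident sites stay finite). The p-value
#' is a two-sided permutation test: p = min(1, 2 * min(p_lower, p_upper))
#' with the add-one correction, so the smallest attainable p is
#' 2/(n_permutations + 1).
#'
#' @param residuals numeric residual vector (non-degenerate).
#' @param coords two-column matrix or data frame of site coordinates.
#' @param n_permutations number of permutations (999 default).
#' @param seed integer seed for the permutation draw.
#' @param floor distance floor in metres.
#' @return list `I, p, n_permutations`.
#' @export
morans_i <- function(residuals, coords, n_permutations = 999, seed = 1, floor = 1) {
  z <- residuals - mean(residuals)
  n <- length(z)
  if (n < 4L) abort_lur("lur_validation_error", "Moran's I needs >= 4 sites")
  if (stats::sd(residuals) == 0) {
    abort_lur("lur_validation_error", "residuals have zero variance")
  }
  coords <- as.matrix(coords[, c(1, 2)])
  w <- inverse_distance_weights(coords, floor)
  s0 <- sum(w)
  denom <- sum(z^2)
  i_obs <- (n / s0) * sum(z * (w %*% z)) / denom
  perm_i <- with_substream(seed, "moran_permutations", {
    Z <- vapply(seq_len(n_permutations), function(b) z[sample.int(n)], numeric(n))
    (n / s0) * colSums(Z * (w %*% Z)) / denom
  })
  p_up <- (1 + sum(perm_i >= i_obs)) / (n_permutations + 1)
  p_dn <- (1 + sum(perm_i <= i_obs)) / (n_permutations + 1)
  list(I = i_obs, p = min(1, 2 * min(p_up, p_dn)), n_permutations = n_permutations)
}

#' Full validation report for a fitted LUR model
#'
#' Combines in-sample fit quality (R2, RMSE, NMB), LOOCV metrics, and
#' residual spatial autocorrelation. The Moran's I check passes when its
#' permutation p-value exceeds 0.05.
#'
#' @param fit a `lur_fit`.
#' @param pm its `predictor_matrix`.
#' @param response the observed response.
#' @param coords two-column site coordinates aligned with `pm` rows.
#' @param n_permutations,seed,floor passed to [morans_i()].
#' @param r2_method passed to [loocv()].
#' @return a `validation_report` list; also attached to the returned fit as
#'   `fit$validation` when assigned back by the caller.
#' @export
validate_lur <- function(fit, pm, response, coords, n_permutations = 999,
                         seed = 1, floor = 1, r2_method = "pearson") {
  y <- as.numeric(response)
  fitted <- if (!is.null(fit$fitted)) {
    fit$fitted
  } else {
    predict_from_matrix(fit, pm)
  }
  em <- error_metrics(y, fitted)
  cv <- loocv(fit, pm, response, r2_method = r2_method)
  resid <- y - fitted
  mi <- morans_i(resid, coords, n_permutations = n_permutations, seed = seed, floor = floor)
  structure(
    list(
      model_r2 = fit$r_squared, rmse = em$rmse, nmb = em$nmb,
      loocv_r2 = cv$loocv_r2, loocv_rmse = cv$loocv_rmse, loocv_nmb = cv$loocv_nmb,
      loocv_predictions = cv$predictions,
      morans_i = mi$I, morans_p = mi$p, morans_pass = mi$p > 0.05,
      n_sites = length(y)
    ),
    class = "validation_report"
  )
}

predict_from_matrix <- function(fit, pm) {
  terms <- fit$terms$name
  if (length(terms) == 0L) {
    return(rep(fit$intercept, nrow(pm$values)))
  }
  fit$intercept + as.numeric(pm$values[, terms, drop = FALSE] %*% fit$terms$coefficient)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<validation_report> n = %d\n",
      "  model R2 %.3f | RMSE %.3g | NMB %.3g\n",
      "  LOOCV R2 %.3f | RMSE %.3g | NMB %.3g\n",
      "  Moran's I %.4f (p = %.3f, %s)\n"
    ),
    x$n_sites, x$model_r2, x$rmse, x$nmb,
    x$loocv_r2, x$loocv_rmse, x$loocv_nmb,
    x$morans_i, x$morans_p, if (x$morans_pass) "no residual autocorrelation detected" else "autocorrelated"
  ))
  invisible(x)
}

#' Write LOOCV observed-vs-predicted pairs and a scatter plot
#'
#' The CSV has one row per fold (`site_id, observed, predicted`); the plot
#' shows observed against predicted with a dotted 1:1 line and per-area
#' symbols when an `area` column is supplied.
#'
#' @param report a `validation_report`.
#' @param response observed values.
#' @param sites site table (`site_id`, optionally `area`).
#' @param csv_path,plot_path output paths (`plot_path = NULL` skips the
#'   plot).
#' @return paths, invisibly.
#' @export
write_validation_outputs <- function(report, response, sites, csv_path, plot_path = NULL) {
  df <- data.frame(
    site_id = sites$site_id, observed = as.numeric(response),
    predicted = report$loocv_predictions
  )
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 720, height = 720)
    on.exit(grDevices::dev.off())
    pch <- if ("area" %in% names(sites)) as.integer(factor(sites$area)) else 1L
    lim <- range(c(df$observed, df$predicted))
    graphics::plot(df$predicted, df$observed,
      pch = pch, xlim = lim, ylim = lim,
      xlab = "Predicted (ug/m3)", ylab = "Observed (ug/m3)",
      main = "Leave-one-out cross-validation"
    )
    graphics::abline(0, 1, lty = 3)
    if ("area" %in% names(sites)) {
      lv <- levels(factor(sites$area))
      graphics::legend("topleft", legend = lv, pch = seq_along(lv), bty = "n")
    }
  }
  invisible(c(csv_path, plot_path))
}
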