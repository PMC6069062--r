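make_design <- function(n, k, seed, signs = NULL) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * k), n, k)
  colnames(X) <- sprintf("P%02d", seq_len(k))
  signs <- signs %||% stats::setNames(rep("+", k), colnames(X))
  raw_matrix(X, signs)
}

test_that("candidate screening applies the strict 10% non-null rule and drops constants", {
  n <- 95
  X <- cbind(
    sparse9 = c(rep(1, 9), rep(0, n - 9)), # 9.5% non-null -> dropped
    sparse11 = c(rep(1, 11), rep(0, n - 11)), # 11.6% non-null -> kept
    allzero = rep(0, n),
    allsame = rep(3.3, n), # constant, dense -> dropped
    dense = stats::rnorm(n)
  )
  pm <- raw_matrix(X, stats::setNames(rep("+", 5), colnames(X)))
  kept <- screen_candidates(pm)
  expect_setequal(kept, c("sparse11", "dense"))
  empty <- raw_matrix(X[0, , drop = FALSE], stats::setNames(rep("+", 5), colnames(X)))
  expect_error(screen_candidates(empty), class = "lur_screen_error")
})

test_that("forward selection handles exact fits and sign vetoes", {
  n <- 30
  set.seed(1)
  x <- stats::rnorm(n)
  pm1 <- raw_matrix(matrix(x, ncol = 1, dimnames = list(NULL, "P01")), c(P01 = "+"))
  fit <- forward_select(2 * x + 1, pm1, "P01")
  expect_equal(fit$terms$name, "P01")
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$terms$coefficient, 2, tolerance = 1e-12)

  # slope contradicts the declared direction: intercept-only model
  pm2 <- raw_matrix(matrix(x, ncol = 1, dimnames = list(NULL, "P01")), c(P01 = "-"))
  fit2 <- forward_select(2 * x + 1, pm2, "P01")
  expect_equal(nrow(fit2$terms), 0L)
  expect_true(any(fit2$selection_trace$reason == "wrong sign"))
  # an empty candidate set is a valid intercept-only outcome, not an error
  fit3 <- forward_select(2 * x + 1, pm1, character(0))
  expect_equal(nrow(fit3$terms), 0L)
  expect_equal(fit3$intercept, mean(2 * x + 1))
})

test_that("step-1 choice matches the all-single-predictor enumeration oracle on seeded data", {
  for (seed in 1:15) {
    pm <- make_design(20, 5, seed)
    set.seed(seed + 1000)
    y <- 2 * pm$values[, "P01"] + stats::rnorm(20, 0, 0.8)
    fit <- forward_select(y, pm)
    # oracle: best eligible single-predictor R2 by brute force
    r2s <- vapply(colnames(pm$values), function(nm) {
      f <- stats::lm(y ~ pm$values[, nm])
      if (sign(stats::coef(f)[2]) != 1) return(-Inf) # '+' expected everywhere
      summary(f)$r.squared
    }, numeric(1))
    best <- names(r2s)[r2s == max(r2s)][1] # lexicographic tie-break
    first <- fit$selection_trace[fit$selection_trace$accepted & fit$selection_trace$step == 1, ]
    expect_identical(first$candidate, best)
    expect_identical(first$candidate, "P01")
  }
})

test_that("selection trace is monotone with increments above the cut-off, and fits are deterministic", {
  pm <- make_design(60, 8, 7)
  set.seed(99)
  y <- pm$values[, "P01"] - 0.8 * pm$values[, "P02"] + stats::rnorm(60, 0, 0.7)
  pm$specs$P02$expected_sign <- "-"
  fit <- fit_lur(y, pm)
  steps <- fit$selection_trace[fit$selection_trace$accepted, ]
  expect_true(all(diff(steps$r2) > 0))
  expect_true(all(fit$terms$inc_r2 >= 0.01 - 1e-12))
  expect_true(all(sign(fit$terms$coefficient) == ifelse(fit$terms$expected_sign == "+", 1, -1)))
  expect_true(all(fit$terms$p_value < 0.1))
  expect_true(all(fit$terms$vif < 3))

  fit2 <- fit_lur(y, pm)
  expect_identical(summary(fit)$predictors, summary(fit2)$predictors)
  expect_identical(fit$selection_trace, fit2$selection_trace)
})

test_that("VIF matches closed forms and the auxiliary-regression oracle", {
  n <- 400
  set.seed(3)
  a <- stats::rnorm(n)
  b <- stats::rnorm(n)
  X <- cbind(A = a, B = b)
  expect_equal(unname(vif(X)["A"]), 1 / (1 - summary(stats::lm(a ~ b))$r.squared))

  # an exactly 0.9-correlated pair has VIF 1/(1-0.81)
  u <- stats::rnorm(n)
  x1 <- u
  x2 <- 0.9 * u + sqrt(1 - 0.81) * stats::rnorm(n)
  # force exact sample correlation via residualization
  e <- stats::residuals(stats::lm(x2 ~ x1))
  x2 <- 0.9 * stats::sd(x1) * (x1 - mean(x1)) / stats::sd(x1) + sqrt(1 - 0.81) * stats::sd(x1) * e / stats::sd(e)
  r <- stats::cor(x1, x2)
  expect_equal(r, 0.9, tolerance = 1e-12)
  v <- vif(cbind(X1 = x1, X2 = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)

  # single column: VIF 1 by definition; three columns: auxiliary OLS oracle
  expect_equal(unname(vif(X[, 1, drop = FALSE])), 1)
  Z <- cbind(A = a, B = b + 0.5 * a, C = stats::rnorm(n) - 0.3 * b)
  v3 <- vif(Z)
  for (j in 1:3) {
    r2 <- summary(stats::lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(unname(v3[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
})

test_that("diagnostic pruning drops collinear then insignificant terms and flags influential sites", {
  n <- 80
  set.seed(13)
  u <- stats::rnorm(n)
  x1 <- u + stats::rnorm(n, 0, 0.2)
  x2 <- u + stats::rnorm(n, 0, 0.2) # highly correlated with x1
  x3 <- stats::rnorm(n)
  X <- cbind(T1 = x1, T2 = x2, T3 = x3)
  pm <- raw_matrix(X, c(T1 = "+", T2 = "+", T3 = "+"))
  y <- x1 + x2 + x3 + stats::rnorm(n, 0, 0.5)
  raw_fit <- forward_select(y, pm, colnames(X), min_gain = 0.001)
  if (all(c("T1", "T2") %in% raw_fit$terms$name)) {
    pruned <- prune_diagnostics(raw_fit, pm, y)
    expect_false(all(c("T1", "T2") %in% pruned$terms$name))
    expect_true(all(pruned$terms$vif < 3))
    expect_true(any(grepl("VIF", pruned$prune_log)))
  }

  # a p-value straggler is pruned after the VIF pass
  set.seed(14)
  Xp <- cbind(S1 = stats::rnorm(n), S2 = stats::rnorm(n))
  pmp <- raw_matrix(Xp, c(S1 = "+", S2 = "+"))
  yp <- Xp[, "S1"] + 0.001 * Xp[, "S2"] + stats::rnorm(n, 0, 0.4)
  ff <- forward_select(yp, pmp, colnames(Xp), min_gain = 1e-9)
  if ("S2" %in% ff$terms$name) {
    pp <- prune_diagnostics(ff, pmp, yp)
    expect_false("S2" %in% pp$terms$name)
  }

  # Cook's D flag against the definitional leave-one-out oracle
  set.seed(15)
  xs <- stats::rnorm(25)
  ys <- xs + stats::rnorm(25, 0, 0.2)
  ys[25] <- ys[25] + 8 # one wildly influential site
  pmc <- raw_matrix(matrix(xs, ncol = 1, dimnames = list(NULL, "C1")), c(C1 = "+"))
  fitc <- prune_diagnostics(forward_select(ys, pmc, "C1"), pmc, ys)
  f <- stats::lm(ys ~ xs)
  p <- 2
  s2 <- sum(stats::residuals(f)^2) / (25 - p)
  d_oracle <- vapply(1:25, function(i) {
    fi <- stats::lm(ys[-i] ~ xs[-i])
    yhat_full <- stats::fitted(f)
    yhat_drop <- stats::coef(fi)[1] + stats::coef(fi)[2] * xs
    sum((yhat_full - yhat_drop)^2) / (p * s2)
  }, numeric(1))
  expect_equal(fitc$max_cooks_d, max(d_oracle), tolerance = 1e-8)
  if (max(d_oracle) >= 1) {
    expect_identical(fitc$influential_sites, pmc$site_id[which.max(d_oracle)])
  }
})

test_that("lur fits round-trip through JSON with coefficients and specs intact", {
  st <- synthetic_study(tiny_config(n_sites = 20, noise_sd = 0, ref_gap_fraction = 0, lost_fraction = 0))
  specs <- lapply(st$config$true_model$terms, `[[`, "spec")
  pm <- build_predictor_matrix(specs, st$layers, st$sites, st$raster)
  y <- st$truth$true_site_means$annual
  fit <- fit_lur(y, pm, pollutant = "no2", season = "annual")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fit.json")
  write_lur_json(fit, path)
  back <- read_lur_json(path)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(back$terms$coefficient, fit$terms$coefficient, tolerance = 1e-12)
  expect_identical(names(back$specs), names(fit$specs))
  expect_equal(back$r_squared, fit$r_squared, tolerance = 1e-12)
})
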