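test_that("fit_ols recovers exact and null relationships", {
  set.seed(1)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + 3
  fit <- suppressWarnings(fit_ols(X, y))    # perfect fit
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$resid_sd, 1e-8)
  expect_equal(unname(fit$coefficients), c(3, 1, -2, 0.5), tolerance = 1e-8)

  # y orthogonal to X by construction: regress out X first
  y0 <- residuals(lm(rnorm(40) ~ X))
  fit0 <- fit_ols(X, y0)
  expect_equal(unname(fit0$coefficients[-1]), rep(0, 3), tolerance = 1e-10)
})

test_that("fit_ols slope is within 3 SE of a planted coefficient", {
  set.seed(2)
  x <- rnorm(200)
  y <- 2 * x + rnorm(200)
  fit <- fit_ols(matrix(x, dimnames = list(NULL, "x")), y)
  expect_lt(abs(fit$coefficients["x"] - 2), 3 * fit$se["x"])
  # R2 equals squared correlation of fitted with observed
  expect_equal(fit$r2, cor(fit$fitted, y)^2, tolerance = 1e-12)
  expect_error(fit_ols(cbind(x, x), y), "singular")
})

test_that("best-subset enumeration selects the planted predictors", {
  coh <- planted_cohort(n = 500, rho2 = 0.3, mode = "linear", seed = 21)
  cands <- c("age", "bmi_pre", unlist(mmpi2_scale_families()))
  res <- best_subset_search(coh[cands], coh$ewl, max_size = 4)
  expect_setequal(res$selected$variables, study_vars)
  expect_true(all(diff(-res$table$r2) >= -1e-12))  # sorted by R2 desc
})

test_that("best-subset is invariant to candidate order and nests correctly", {
  coh <- planted_cohort(n = 200, rho2 = 0.3, mode = "linear", seed = 22)
  cands <- c("age", "Pa", "Asp", "TpA", "D", "Hs")
  a <- best_subset_search(coh[cands], coh$ewl, max_size = 3)
  b <- best_subset_search(coh[rev(cands)], coh$ewl, max_size = 3)
  expect_identical(a$table, b$table)
  # full cap reproduces the full-model R2 at the top of the R2 ordering
  full <- best_subset_search(coh[cands], coh$ewl, max_size = length(cands))
  fit_all <- fit_ols(coh[cands], coh$ewl)
  expect_equal(max(full$table$r2), fit_all$r2, tolerance = 1e-10)
  # adding a variable never decreases R2 along a nested chain
  r2_by_size <- tapply(full$table$r2, full$table$size, max)
  expect_true(all(diff(r2_by_size) >= -1e-12))
})

test_that("single perfect candidate is selected with R2 = 1", {
  set.seed(3)
  y <- rnorm(50)
  cands <- data.frame(self = y, junk = rnorm(50))
  res <- suppressWarnings(best_subset_search(cands, y, max_size = 1))
  expect_equal(res$selected$variables, "self")
  expect_equal(res$selected$r2, 1, tolerance = 1e-10)
})

test_that("no-passing-subset yields a flagged empty selection", {
  set.seed(4)
  cands <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rnorm(30)
  res <- best_subset_search(cands, y, max_size = 2, alpha = 1e-6)
  expect_null(res$selected)
  expect_false(any(res$table$passes))
})

test_that("VIF matches the closed form and the auxiliary-regression oracle", {
  # two columns with correlation 0.6 -> VIF = 1/(1-0.36)
  set.seed(5)
  z <- MASS::mvrnorm(4000, c(0, 0), matrix(c(1, .6, .6, 1), 2),
                     empirical = TRUE)
  v <- collinearity_vif(z)
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-10)

  # random 5-column designs vs auxiliary regressions
  for (i in 1:5) {
    X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, letters[1:5]))
    X[, 2] <- X[, 1] * 0.5 + X[, 2]
    got <- collinearity_vif(X)
    oracle <- vapply(1:5, function(j) {
      r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    expect_equal(unname(got), oracle, tolerance = 1e-8)
  }

  # orthogonal (centred) columns -> VIF 1; duplicated column -> infinite flag
  Q <- unclass(poly(1:20, 5))
  colnames(Q) <- letters[1:5]
  expect_equal(unname(collinearity_vif(Q)), rep(1, 5), tolerance = 1e-8)
  expect_warning(vd <- collinearity_vif(cbind(a = Q[, 1], b = Q[, 1])),
                 "collinearity")
  expect_true(all(is.infinite(vd)))
})

test_that("partial correlations match the residual-on-residual oracle", {
  set.seed(6)
  X <- matrix(rnorm(240), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 2] + 0.4 * X[, 1]
  y <- drop(X %*% c(1, 0.5, 0)) + rnorm(80)
  got <- partial_correlations(X, y)
  oracle <- vapply(1:3, function(j) {
    ry <- residuals(lm(y ~ X[, -j]))
    rx <- residuals(lm(X[, j] ~ X[, -j]))
    cor(ry, rx)
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-8)

  # single predictor: partial equals zero-order
  g1 <- partial_correlations(X[, 1, drop = FALSE], y)
  expect_equal(unname(g1), cor(X[, 1], y), tolerance = 1e-10)
})

test_that("residual diagnostics behave as tests of their null", {
  # type-I error of normality tests near 5% under Gaussian residuals
  set.seed(7)
  n_rej_jb <- 0; n_rej_li <- 0; reps <- 200
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "x"))
    y <- drop(X) + rnorm(500)
    d <- residual_diagnostics(fit_ols(X, y), X, y)
    n_rej_jb <- n_rej_jb + (d$jarque_bera_p < 0.05)
    n_rej_li <- n_rej_li + (d$lilliefors_p < 0.05)
  }
  expect_lt(abs(n_rej_jb / reps - 0.05), 0.05)
  expect_lt(abs(n_rej_li / reps - 0.05), 0.05)
})

test_that("Jarque-Bera has power against skewed residuals", {
  set.seed(8)
  rej <- 0
  for (i in 1:40) {
    X <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "x"))
    y <- drop(X) + rexp(500)   # heavily skewed errors
    d <- residual_diagnostics(fit_ols(X, y), X, y)
    rej <- rej + (d$jarque_bera_p < 0.05)
  }
  expect_gte(rej / 40, 0.95)
})

test_that("runs test rejects alternating-sign residuals", {
  x <- rep(c(1, -1), 50)
  expect_lt(ewlpredict:::runs_test_(x)$p.value, 1e-6)
  # balanced random signs: no rejection most of the time
  set.seed(9)
  p <- replicate(50, ewlpredict:::runs_test_(rnorm(100))$p.value)
  expect_gt(mean(p > 0.05), 0.8)
})

test_that("interaction design has the forced width and finds planted products", {
  set.seed(10)
  X2 <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  f2 <- fit_interactions(X2, rnorm(50))
  expect_equal(length(f2$variables), 3)       # 2 mains + 1 product

  X7 <- matrix(rnorm(1400), 200, 7,
               dimnames = list(NULL, paste0("v", 1:7)))
  f7 <- fit_interactions(X7, rnorm(200))
  expect_equal(length(f7$variables), 7 + choose(7, 2))   # width 28

  # planted product term raises R2 by its planted share
  n <- 2000
  Xp <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- Xp[, 1] + 0.8 * Xp[, 1] * Xp[, 2] + rnorm(n)
  main_r2 <- fit_ols(Xp, y)$r2
  int_r2 <- fit_interactions(Xp, y)$r2
  planted_gain <- var(0.8 * Xp[, 1] * Xp[, 2]) / var(y)
  expect_lt(abs((int_r2 - main_r2) - planted_gain), 0.02)
})

test_that("predict_linear reproduces printed-coefficient arithmetic", {
  fit <- structure(list(
    variables = c("age", "Pa", "Asp", "TpA"),
    coefficients = c(`(Intercept)` = 96.977, age = -0.259, Pa = -0.510,
                     Asp = -0.626, TpA = 0.364)), class = "subset_fit")
  p <- predict_linear(fit, data.frame(age = 40, Pa = 50, Asp = 50, TpA = 50))
  expect_equal(p, 48.017, tolerance = 1e-12)
  p2 <- predict_linear(fit, data.frame(age = 40, Pa = 50, Asp = 50, TpA = 60))
  expect_equal(p2 - p, 3.64, tolerance = 1e-12)
  expect_equal(predict_linear(fit, data.frame(age = 0, Pa = 0, Asp = 0,
                                              TpA = 0)), 96.977)
  expect_error(predict_linear(fit, data.frame(age = 40)), "missing")
})
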