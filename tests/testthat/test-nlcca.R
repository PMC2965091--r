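test_that("mlp_forward computes the layered affine/tanh map", {
  p <- ewlpredict:::mlp_params(W1 = matrix(0, 3, 2), b1 = rep(0, 3),
                               w2 = rep(0, 3), b2 = 0.7, "tanh")
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(mlp_forward(p, X), rep(0.7, 5))   # all-zero weights

  # identity activation collapses to an affine map
  set.seed(1)
  q <- ewlpredict:::mlp_params(W1 = matrix(rnorm(6), 3, 2),
                               b1 = rnorm(3), w2 = rnorm(3), b2 = rnorm(1),
                               "identity")
  a_vec <- drop(t(q$w2) %*% q$W1)                # collapsed slope
  a0 <- sum(q$w2 * q$b1) + q$b2                  # collapsed intercept
  expect_equal(mlp_forward(q, X), drop(X %*% a_vec) + a0, tolerance = 1e-12)

  # tanh hidden outputs are bounded
  r <- ewlpredict:::mlp_params(W1 = matrix(50, 4, 2), b1 = rep(0, 4),
                               w2 = rep(1, 4), b2 = 0, "tanh")
  expect_true(all(abs(mlp_forward(r, X)) <= 4))
  expect_error(mlp_forward(q, matrix(0, 2, 3)), "width")
})

test_that("cost_jm matches hand arithmetic", {
  set.seed(2)
  v <- drop(scale(rnorm(50)))        # mean 0, sample SD 1
  expect_equal(cost_jm(v, v), -1, tolerance = 1e-12)
  u <- drop(scale(residuals(lm(rnorm(50) ~ v))))
  expect_equal(cost_jm(u, v), 0, tolerance = 1e-12)
  # u = 2v: corr 1, var(u) = 4 -> penalty (4-1)^2
  expect_equal(cost_jm(2 * v, v, penalty_weight = 1), -1 + 9,
               tolerance = 1e-12)
  expect_equal(cost_jm(2 * v, v, penalty_weight = 0.5), -1 + 4.5,
               tolerance = 1e-12)
  expect_error(cost_jm(rep(1, 10), v[1:10]), "degenerate")
})

test_that("analytic gradient of J_m matches finite differences", {
  set.seed(3)
  X <- matrix(rnorm(90), 30, 3)
  y <- matrix(rnorm(30), 30, 1)
  nh <- 3
  np <- ewlpredict:::n_params_(3, nh) + ewlpredict:::n_params_(1, nh)
  th <- rnorm(np, sd = 0.4)
  ob <- ewlpredict:::jm_objective_(th, X, y, nh, 1)
  num <- vapply(seq_len(np), function(i) {
    e <- th; h <- 1e-6; e[i] <- e[i] + h
    (ewlpredict:::jm_objective_(e, X, y, nh, 1)$value - ob$value) / h
  }, numeric(1))
  expect_equal(ob$gradient, num, tolerance = 1e-3)
})

test_that("noiseless monotone outcome is recovered almost perfectly", {
  set.seed(4)
  x <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
  y <- matrix(drop(scale(tanh(1.2 * x))), 200, 1)
  runs <- lapply(1:10, function(s)
    train_single_run(scale(x), y, n_hidden = 2, seed = s))
  ok <- Filter(function(r) !r$failed && !r$rejected, runs)
  expect_gt(length(ok), 0)
  expect_true(any(vapply(ok, function(r) r$corr_train, numeric(1)) >= 0.99))
})

test_that("single runs are deterministic and reject null structure", {
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3)
  y <- matrix(rnorm(100), 100, 1)
  a <- train_single_run(X, y, n_hidden = 2, seed = 7)
  b <- train_single_run(X, y, n_hidden = 2, seed = 7)
  expect_identical(a, b)
  # y independent of X: validation correlation near zero on average
  vals <- vapply(1:8, function(s)
    train_single_run(X, y, n_hidden = 2, seed = s)$corr_val, numeric(1))
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.3)
})

test_that("multistart returns accepted best run with standardized scores", {
  coh <- planted_cohort(n = 300, rho2 = 0.5^2, seed = 31)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  m <- train_multistart(sx$values, sy$values, n_hidden = 2, n_runs = 30,
                        seed = 3)
  expect_s3_class(m, "dual_mlp")
  expect_lte(m$training$accepted_runs, m$training$n_runs)
  sc <- score_dual_mlp(m, sx$values, sy$values)
  # constraint satisfaction on the training portion of the accepted run
  ti <- m$training$train_idx
  expect_lt(abs(mean(sc$u[ti])), 0.01)
  expect_lt(abs(mean(sc$v[ti])), 0.01)
  expect_lt(abs(sd(sc$u[ti]) - 1), 0.05)
  expect_lt(abs(sd(sc$v[ti]) - 1), 0.05)
  # sign convention: higher v means higher EWL
  expect_gt(cor(sc$v, coh$ewl), 0)
  # affine y-net: |cor(u,v)| = |cor(u, y)| exactly
  expect_equal(abs(cor(sc$u, sc$v)), abs(cor(sc$u, coh$ewl)),
               tolerance = 1e-12)
})

test_that("multistart is deterministic for a fixed master seed", {
  coh <- planted_cohort(n = 150, rho2 = 0.3, seed = 32)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  m1 <- train_multistart(sx$values, sy$values, n_hidden = 2, n_runs = 8,
                         seed = 9, allow_unaccepted = TRUE)
  m2 <- train_multistart(sx$values, sy$values, n_hidden = 2, n_runs = 8,
                         seed = 9, allow_unaccepted = TRUE)
  expect_identical(m1$training, m2$training)
  expect_identical(m1$net_x, m2$net_x)
})

test_that("nlcca attains at least the linear multiple correlation", {
  coh <- planted_cohort(n = 300, rho2 = 0.36, mode = "linear", seed = 33)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  m <- train_multistart(sx$values, sy$values, n_hidden = 2, n_runs = 40,
                        seed = 5, allow_unaccepted = TRUE)
  ols_r <- sqrt(fit_ols(coh[study_vars], coh$ewl)$r2)
  expect_gte(m$training$corr_all, ols_r - 0.02)
})

test_that("all-rejected multistart raises the advisory error", {
  coh <- planted_cohort(n = 100, rho2 = 0.4, seed = 34)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  # find a seed whose single run is rejected, then demand n_runs = 1
  for (s in 1:50) {
    r <- train_single_run(sx$values, sy$values, n_hidden = 4, seed = s)
    if (r$rejected) break
  }
  expect_true(r$rejected)
  # replicate that run inside multistart via its derived seed:
  # simplest guarantee: run multistart with n_runs = 1 repeatedly until the
  # derived seed yields a rejected run, asserting the error class
  err_seen <- FALSE
  for (ms in 1:30) {
    out <- tryCatch(train_multistart(sx$values, sy$values, n_hidden = 4,
                                     n_runs = 1, seed = ms),
                    error = function(e) e)
    if (inherits(out, "error")) {
      err_seen <- TRUE
      expect_match(conditionMessage(out), "rejected")
      break
    }
  }
  expect_true(err_seen)
})

test_that("hidden-size selection follows the diminishing-returns rule", {
  # strong linear truth: one tanh unit suffices, further units add noise
  coh <- planted_cohort(n = 500, rho2 = 0.81, mode = "linear", seed = 35)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  sel <- select_hidden_size(sx$values, sy$values, candidate_sizes = 1:3,
                            improvement_threshold = 0.01,
                            n_runs = 12, seed = 2, allow_unaccepted = TRUE)
  expect_equal(sel$selected, 1)
  expect_equal(nrow(sel$trace), 3)
  # an impossible threshold keeps every increment "appreciable", so the
  # largest candidate is returned
  sel0 <- select_hidden_size(sx$values, sy$values, candidate_sizes = 1:2,
                             improvement_threshold = -Inf,
                             n_runs = 5, seed = 2, allow_unaccepted = TRUE)
  expect_equal(sel0$selected, 2)
})

test_that("an additive two-bump response needs at least two hidden units", {
  set.seed(12)
  n <- 400
  x <- matrix(runif(n, -3, 3), n, 1, dimnames = list(NULL, "x"))
  bumps <- tanh(3 * (x + 1.5)) - tanh(3 * (x - 1.5))   # two saturating steps
  y <- cbind(ewl = drop(scale(bumps)))
  sel <- select_hidden_size(standardize(x)$values, y, candidate_sizes = 1:3,
                            improvement_threshold = 0.01,
                            n_runs = 10, seed = 3, allow_unaccepted = TRUE)
  expect_gte(sel$selected, 2)
})

test_that("scrambling y at scoring time changes v but not u", {
  coh <- planted_cohort(n = 150, rho2 = 0.3, seed = 36)
  sx <- standardize(coh[study_vars]); sy <- standardize(cbind(ewl = coh$ewl))
  m <- train_multistart(sx$values, sy$values, n_hidden = 2, n_runs = 10,
                        seed = 4)
  sc1 <- score_dual_mlp(m, sx$values, sy$values)
  sc2 <- score_dual_mlp(m, sx$values, sy$values[sample(150), , drop = FALSE])
  expect_identical(sc1$u, sc2$u)
  expect_false(identical(sc1$v, sc2$v))
})
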