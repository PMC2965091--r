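#' Dual-MLP correlation maximization (nonlinear CCA)
#'
#' Two small feed-forward networks are trained jointly: an x-network with
#' tanh hidden units maps the selected predictors to a nonlinear score u,
#' and a y-network with identity hidden units maps EWL to a linear score
#' v.  Minimizing the modified cost
#' \deqn{J_m = -cor(u, v) + \lambda [\bar u^2 + \bar v^2 +
#'   (var(u)-1)^2 + (var(v)-1)^2]}
#' maximizes the correlation between the scores subject to soft zero-mean
#' / unit-variance constraints.  Because the y-network is affine in its
#' scalar input, |cor(u, v)| = |cor(u, y)| exactly, so the construction is
#' a nonlinear analogue of the multiple correlation of a regression model.
#'
#' @name nlcca
NULL

# ---- parameter layout -------------------------------------------------

# A network is a list: W1 (hidden x inputs), b1 (hidden), w2 (hidden),
# b2 (scalar), activation ("tanh" | "identity").

mlp_params <- function(W1, b1, w2, b2, activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  W1 <- as.matrix(W1)
  stopifnot(length(b1) == nrow(W1), length(w2) == nrow(W1), length(b2) == 1)
  if (!all(is.finite(W1), is.finite(b1), is.finite(w2), is.finite(b2)))
    stop("MLP parameters must be finite", call. = FALSE)
  list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
       b2 = as.numeric(b2), activation = activation)
}

n_params_ <- function(n_inputs, n_hidden) n_hidden * n_inputs + 2 * n_hidden + 1

# theta layout per net: [vec(W1) | b1 | w2 | b2]
unpack_net_ <- function(theta, n_inputs, n_hidden, activation) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(n_hidden * n_inputs)], n_hidden, n_inputs)
  i <- i + n_hidden * n_inputs
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  w2 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- theta[i + 1]
  mlp_params(W1, b1, w2, b2, activation)
}

pack_net_ <- function(net) c(as.vector(net$W1), net$b1, net$w2, net$b2)

#' Forward pass of one MLP
#'
#' score = w2 . act(W1 x + b1) + b2 per record, with act = tanh or the
#' identity.
#'
#' @param params Network parameter list (`W1`, `b1`, `w2`, `b2`,
#'   `activation`) as stored in a trained model.
#' @param inputs Numeric matrix, one row per record; width must match
#'   `ncol(params$W1)`.
#' @return Numeric score vector, one value per row.
#' @export
mlp_forward <- function(params, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != ncol(params$W1))
    stop("input width ", ncol(inputs), " does not match network (",
         ncol(params$W1), ")", call. = FALSE)
  A <- inputs %*% t(params$W1) + rep(params$b1, each = nrow(inputs))
  H <- if (params$activation == "tanh") tanh(A) else A
  drop(H %*% params$w2 + params$b2)
}

# forward that also returns hidden activations, for backprop
mlp_forward_h_ <- function(params, inputs) {
  A <- inputs %*% t(params$W1) + rep(params$b1, each = nrow(inputs))
  H <- if (params$activation == "tanh") tanh(A) else A
  list(H = H, score = drop(H %*% params$w2 + params$b2))
}

#' Modified training cost J_m
#'
#' Negative Pearson correlation of the two score vectors plus quadratic
#' penalties keeping each score at zero mean and unit (sample) variance.
#'
#' @param u,v Numeric score vectors of equal length >= 3.
#' @param penalty_weight Weight lambda of the constraint penalties
#'   (default 1).
#' @return Scalar cost; -1 is the ideal value (perfect correlation,
#'   constraints met).
#' @export
cost_jm <- function(u, v, penalty_weight = 1) {
  n <- length(u)
  if (length(v) != n || n < 3)
    stop("`u` and `v` must have equal length >= 3", call. = FALSE)
  vu <- stats::var(u); vv <- stats::var(v)
  if (vu == 0 || vv == 0)
    stop("degenerate score: zero variance", call. = FALSE)
  -stats::cor(u, v) + penalty_weight *
    (mean(u)^2 + mean(v)^2 + (vu - 1)^2 + (vv - 1)^2)
}

# joint cost and analytic gradient over packed [theta_x | theta_y]
jm_objective_ <- function(theta, X, y, n_hidden, penalty_weight) {
  p <- ncol(X)
  nx <- n_params_(p, n_hidden)
  net_x <- unpack_net_(theta[seq_len(nx)], p, n_hidden, "tanh")
  net_y <- unpack_net_(theta[-seq_len(nx)], 1, n_hidden, "identity")
  fx <- mlp_forward_h_(net_x, X)
  fy <- mlp_forward_h_(net_y, y)
  u <- fx$score; v <- fy$score
  n <- length(u); m <- n - 1
  su <- u - mean(u); sv <- v - mean(v)
  vu <- sum(su^2) / m; vv <- sum(sv^2) / m
  if (vu < 1e-12 || vv < 1e-12)
    return(list(value = 2 + penalty_weight * ((vu - 1)^2 + (vv - 1)^2),
                gradient = NULL))
  C <- sum(su * sv) / m
  r <- C / sqrt(vu * vv)
  J <- -r + penalty_weight *
    (mean(u)^2 + mean(v)^2 + (vu - 1)^2 + (vv - 1)^2)
  # dJ/du and dJ/dv
  dr_du <- (sv - (C / vu) * su) / (m * sqrt(vu * vv))
  dr_dv <- (su - (C / vv) * sv) / (m * sqrt(vu * vv))
  g_u <- -dr_du + penalty_weight * (2 * mean(u) / n + 4 * (vu - 1) * su / m)
  g_v <- -dr_dv + penalty_weight * (2 * mean(v) / n + 4 * (vv - 1) * sv / m)
  # backprop x-net (tanh)
  Gx <- (g_u %o% net_x$w2) * (1 - fx$H^2)
  grad_x <- c(as.vector(t(Gx) %*% X), colSums(Gx),
              drop(crossprod(fx$H, g_u)), sum(g_u))
  # backprop y-net (identity)
  Gy <- g_v %o% net_y$w2
  grad_y <- c(as.vector(t(Gy) %*% y), colSums(Gy),
              drop(crossprod(fy$H, g_v)), sum(g_v))
  list(value = J, gradient = c(grad_x, grad_y))
}

# uniform +-0.5/sqrt(fan_in) initialization for one net
init_net_ <- function(n_inputs, n_hidden) {
  lim1 <- 0.5 / sqrt(n_inputs)
  lim2 <- 0.5 / sqrt(n_hidden)
  c(stats::runif(n_hidden * n_inputs, -lim1, lim1),   # W1
    stats::runif(n_hidden, -lim1, lim1),              # b1
    stats::runif(n_hidden, -lim2, lim2),              # w2
    stats::runif(1, -lim2, lim2))                     # b2
}

#' One training run of the dual-MLP model
#'
#' Draws a seeded random validation split, initializes both networks from
#' a small uniform distribution, and minimizes [cost_jm()] on the training
#' portion with the BFGS quasi-Newton algorithm using analytic gradients.
#' A run is flagged `rejected` when the score correlation on the
#' validation split is lower than on the training split (overfitting
#' guard), and `failed` when optimization returns non-finite parameters.
#'
#' @param X Standardized predictor matrix.
#' @param y Standardized outcome vector (column).
#' @param n_hidden Hidden units in both networks.
#' @param seed Integer seed for split and initialization.
#' @param validation_fraction Fraction withheld for validation, in
#'   (0, 0.5].
#' @param penalty_weight Constraint penalty weight.
#' @param maxit BFGS iteration cap.
#' @param reltol Relative function-value convergence tolerance of the
#'   quasi-Newton optimizer.
#' @return List: `net_x`, `net_y`, `jm`, `corr_train`, `corr_val`,
#'   `rejected`, `failed`, `converged`, `train_idx`.
#' @export
train_single_run <- function(X, y, n_hidden = 4, seed = 1L,
                             validation_fraction = 0.2,
                             penalty_weight = 1, maxit = 500,
                             reltol = 1e-6) {
  X <- as.matrix(X); y <- as.matrix(y)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 records", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction > 0.5)
    stop("`validation_fraction` must be in (0, 0.5]", call. = FALSE)
  set.seed(seed)
  n_val <- max(2L, round(validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  Xt <- X[train_idx, , drop = FALSE]; yt <- y[train_idx, , drop = FALSE]
  theta0 <- c(init_net_(ncol(X), n_hidden), init_net_(1, n_hidden))
  opt <- tryCatch(
    stats::optim(theta0,
                 fn = function(th) jm_objective_(th, Xt, yt, n_hidden,
                                                 penalty_weight)$value,
                 gr = function(th) {
                   g <- jm_objective_(th, Xt, yt, n_hidden,
                                      penalty_weight)$gradient
                   if (is.null(g)) numeric(length(th)) else g
                 },
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(opt) || any(!is.finite(opt$par)))
    return(list(failed = TRUE, rejected = TRUE, jm = Inf,
                corr_train = NA_real_, corr_val = NA_real_))
  p <- ncol(X)
  nx <- n_params_(p, n_hidden)
  net_x <- unpack_net_(opt$par[seq_len(nx)], p, n_hidden, "tanh")
  net_y <- unpack_net_(opt$par[-seq_len(nx)], 1, n_hidden, "identity")
  u_t <- mlp_forward(net_x, Xt); v_t <- mlp_forward(net_y, yt)
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx, , drop = FALSE]
  u_v <- mlp_forward(net_x, Xv); v_v <- mlp_forward(net_y, yv)
  corr_train <- suppressWarnings(stats::cor(u_t, v_t))
  corr_val <- suppressWarnings(stats::cor(u_v, v_v))
  if (!is.finite(corr_train)) corr_train <- NA_real_
  if (!is.finite(corr_val)) corr_val <- NA_real_
  list(net_x = net_x, net_y = net_y, jm = opt$value,
       corr_train = corr_train, corr_val = corr_val,
       rejected = is.na(corr_val) || is.na(corr_train) ||
         corr_val < corr_train,
       failed = FALSE, converged = opt$convergence == 0,
       train_idx = train_idx)
}

#' Multi-start training of the dual-MLP model
#'
#' Performs `n_runs` independent seeded runs (fresh random initialization
#' and, by default, a fresh validation split per run) and returns the
#' accepted run with the lowest J_m.  The sign indeterminacy (u, v) ->
#' (-u, -v) is resolved so that cor(v, y) >= 0, making higher u mean
#' higher predicted weight loss.  The headline score correlation
#' `corr_all` is computed on all records (training plus validation), the
#' convention under which the full-cohort model summary is reported;
#' `corr_train` / `corr_val` expose the split-wise values.
#'
#' @param X Standardized predictor matrix.
#' @param y Standardized outcome vector.
#' @param n_hidden Hidden units (default 4).
#' @param n_runs Number of random restarts (default 200).
#' @param validation_fraction Validation fraction per run (default 0.2).
#' @param penalty_weight Constraint penalty weight (default 1).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param fixed_split If TRUE the validation split is drawn once (from
#'   `seed`) and reused by every run instead of redrawn per run.
#' @param maxit BFGS iteration cap per run.
#' @param reltol Quasi-Newton convergence tolerance per run.
#' @param allow_unaccepted If TRUE and every run is rejected by the
#'   validation guard, fall back to the lowest-J_m run instead of
#'   erroring; the training record then shows `accepted_runs = 0` and
#'   `unaccepted = TRUE`.  Used by fold-wise cross-validation where run
#'   budgets are small.
#' @return Object of class `dual_mlp`: `net_x`, `net_y`, `n_hidden`, and
#'   `training` (n_runs, accepted_runs, best_jm, corr_all, corr_train,
#'   corr_val, seed, validation_fraction).
#' @export
train_multistart <- function(X, y, n_hidden = 4, n_runs = 200,
                             validation_fraction = 0.2, penalty_weight = 1,
                             seed = 1L, fixed_split = FALSE, maxit = 500,
                             reltol = 1e-6, allow_unaccepted = FALSE) {
  X <- as.matrix(X); y <- as.matrix(y)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  if (fixed_split) {
    n_val <- max(2L, round(validation_fraction * nrow(X)))
    split_val <- sample.int(nrow(X), n_val)
  }
  best <- NULL; best_any <- NULL; accepted <- 0L
  records <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run <- if (fixed_split) {
      train_single_run_fixed_(X, y, n_hidden, run_seeds[i],
                              split_val, penalty_weight, maxit, reltol)
    } else {
      train_single_run(X, y, n_hidden, run_seeds[i],
                       validation_fraction, penalty_weight, maxit, reltol)
    }
    records[[i]] <- run[c("jm", "corr_train", "corr_val",
                          "rejected", "failed")]
    if (!run$failed) {
      if (is.null(best_any) || run$jm < best_any$jm) best_any <- run
      if (!run$rejected) {
        accepted <- accepted + 1L
        if (is.null(best) || run$jm < best$jm) best <- run
      }
    }
  }
  unaccepted <- FALSE
  if (is.null(best)) {
    if (allow_unaccepted && !is.null(best_any)) {
      best <- best_any
      unaccepted <- TRUE
    } else {
      stop("all ", n_runs, " runs were rejected or failed; ",
           "increase `n_runs` or reduce `n_hidden`", call. = FALSE)
    }
  }
  # sign convention: cor(v, y) >= 0
  v <- mlp_forward(best$net_y, y)
  if (stats::cor(v, as.numeric(y)) < 0) {
    for (nm in c("net_x", "net_y")) {
      best[[nm]]$w2 <- -best[[nm]]$w2
      best[[nm]]$b2 <- -best[[nm]]$b2
    }
  }
  u_all <- mlp_forward(best$net_x, X)
  v_all <- mlp_forward(best$net_y, y)
  structure(list(
    net_x = best$net_x, net_y = best$net_y, n_hidden = n_hidden,
    training = list(n_runs = n_runs, accepted_runs = accepted,
                    best_jm = best$jm,
                    corr_all = stats::cor(u_all, v_all),
                    corr_train = best$corr_train,
                    corr_val = best$corr_val, seed = seed,
                    validation_fraction = validation_fraction,
                    train_idx = best$train_idx,
                    unaccepted = unaccepted,
                    runs = records)),
    class = "dual_mlp")
}

# single run with a pre-drawn validation split (fixed-split option)
train_single_run_fixed_ <- function(X, y, n_hidden, seed, val_idx,
                                    penalty_weight, maxit, reltol = 1e-6) {
  n <- nrow(X)
  train_idx <- setdiff(seq_len(n), val_idx)
  set.seed(seed)
  theta0 <- c(init_net_(ncol(X), n_hidden), init_net_(1, n_hidden))
  Xt <- X[train_idx, , drop = FALSE]; yt <- y[train_idx, , drop = FALSE]
  opt <- tryCatch(
    stats::optim(theta0,
                 fn = function(th) jm_objective_(th, Xt, yt, n_hidden,
                                                 penalty_weight)$value,
                 gr = function(th) {
                   g <- jm_objective_(th, Xt, yt, n_hidden,
                                      penalty_weight)$gradient
                   if (is.null(g)) numeric(length(th)) else g
                 },
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(opt) || any(!is.finite(opt$par)))
    return(list(failed = TRUE, rejected = TRUE, jm = Inf,
                corr_train = NA_real_, corr_val = NA_real_))
  p <- ncol(X); nx <- n_params_(p, n_hidden)
  net_x <- unpack_net_(opt$par[seq_len(nx)], p, n_hidden, "tanh")
  net_y <- unpack_net_(opt$par[-seq_len(nx)], 1, n_hidden, "identity")
  u_t <- mlp_forward(net_x, Xt); v_t <- mlp_forward(net_y, yt)
  u_v <- mlp_forward(net_x, X[val_idx, , drop = FALSE])
  v_v <- mlp_forward(net_y, y[val_idx, , drop = FALSE])
  corr_train <- suppressWarnings(stats::cor(u_t, v_t))
  corr_val <- suppressWarnings(stats::cor(u_v, v_v))
  list(net_x = net_x, net_y = net_y, jm = opt$value,
       corr_train = corr_train, corr_val = corr_val,
       rejected = is.na(corr_val) || is.na(corr_train) ||
         corr_val < corr_train,
       failed = FALSE, converged = opt$convergence == 0,
       train_idx = train_idx)
}

#' Score records with a trained dual-MLP model
#'
#' @param model A `dual_mlp`.
#' @param X Standardized predictor matrix (training-fold parameters).
#' @param y Standardized outcome vector (optional; `v` is NULL without
#'   it).
#' @return List with `u` (nonlinear predictor score) and `v` (linear
#'   weight-loss score, or NULL).
#' @export
score_dual_mlp <- function(model, X, y = NULL) {
  stopifnot(inherits(model, "dual_mlp"))
  u <- mlp_forward(model$net_x, as.matrix(X))
  v <- if (is.null(y)) NULL else mlp_forward(model$net_y, as.matrix(y))
  list(u = u, v = v)
}

#' Choose the hidden-layer size by diminishing returns
#'
#' Trains a multi-start model for each candidate size (ascending) and
#' returns the smallest size whose successor improves the score
#' correlation by less than `improvement_threshold`.  With threshold 0 any
#' gain counts and the largest candidate is returned.
#'
#' @param X,y Standardized predictors and outcome.
#' @param candidate_sizes Ascending integer vector of hidden sizes.
#' @param improvement_threshold Minimum correlation gain regarded as
#'   appreciable (default 0.01).
#' @param ... Passed to [train_multistart()] (n_runs, seed, ...).
#' @return List: `selected` size and `trace` (data frame size vs
#'   correlation).
#' @export
select_hidden_size <- function(X, y, candidate_sizes = 1:6,
                               improvement_threshold = 0.01, ...) {
  if (is.unsorted(candidate_sizes))
    stop("`candidate_sizes` must be ascending", call. = FALSE)
  corr <- vapply(candidate_sizes, function(h)
    train_multistart(X, y, n_hidden = h, ...)$training$corr_all,
    numeric(1))
  selected <- candidate_sizes[length(candidate_sizes)]
  for (i in seq_along(candidate_sizes)[-length(candidate_sizes)]) {
    if (corr[i + 1] - corr[i] < improvement_threshold) {
      selected <- candidate_sizes[i]
      break
    }
  }
  list(selected = selected,
       trace = data.frame(n_hidden = candidate_sizes, corr = corr))
}

#' Fit the dual-MLP model to a cohort
#'
#' Convenience wrapper: standardizes the named predictor columns and EWL
#' (sample SD), trains by [train_multistart()], and stores the
#' standardization parameters so new records can be scored consistently.
#'
#' @param cohort A `cohort_table` with planted or observed `ewl`.
#' @param variables Predictor column names.
#' @param ... Passed to [train_multistart()].
#' @return Object of class `nlcca_fit`: `model`, `variables`, `x_params`,
#'   `y_params`, `u`, `v` (scores on the full data).
#' @export
fit_nlcca <- function(cohort, variables, ...) {
  sx <- standardize(cohort[variables])
  sy <- standardize(matrix(cohort$ewl, ncol = 1,
                           dimnames = list(NULL, "ewl")))
  model <- train_multistart(sx$values, sy$values, ...)
  sc <- score_dual_mlp(model, sx$values, sy$values)
  structure(list(model = model, variables = variables,
                 x_params = sx$params, y_params = sy$params,
                 u = sc$u, v = sc$v),
            class = "nlcca_fit")
}

#' Predict the nonlinear score u for new records
#'
#' @param fit An `nlcca_fit`.
#' @param newdata Data frame with the fit variables.
#' @return Numeric u scores (higher = more predicted weight loss).
#' @export
predict_nlcca <- function(fit, newdata) {
  stopifnot(inherits(fit, "nlcca_fit"))
  Z <- standardize(as.data.frame(newdata)[fit$variables],
                   params = fit$x_params)$values
  mlp_forward(fit$model$net_x, Z)
}
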