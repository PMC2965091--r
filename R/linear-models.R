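#' Multiple linear regression with classical inference
#'
#' Fits EWL (or any outcome) on a predictor matrix by ordinary least
#' squares and collects the quantities the analysis reports:
#' unstandardized and standardized coefficients, standard errors, t and
#' two-sided p-values, R2, adjusted R2, residual SD, overall F and model
#' p-value.  Standardized coefficients use the convention
#' \eqn{\beta \cdot SD(x)/SD(y)}.
#'
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param y Numeric outcome vector.
#' @return Object of class `subset_fit`: list with `variables`,
#'   `coefficients` (incl. intercept), `std_coefficients`, `se`, `t`,
#'   `p`, `r2`, `adj_r2`, `resid_sd`, `f`, `model_p`, `n`, `residuals`,
#'   `fitted`, and the underlying `lm` object.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  if (qr(cbind(1, X))$rank < p + 1)
    stop("singular design: predictors are collinear", call. = FALSE)
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("`.y` ~", paste(sprintf("`%s`", colnames(X)),
                                                 collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  beta <- stats::coef(fit)
  sdx <- apply(X, 2, stats::sd)
  sdy <- stats::sd(y)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    variables = colnames(X),
    coefficients = beta,
    std_coefficients = stats::setNames(beta[-1] * sdx / sdy, colnames(X)),
    se = co[, "Std. Error"], t = co[, "t value"], p = co[, "Pr(>|t|)"],
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    resid_sd = sm$sigma,
    f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    model_p = unname(model_p), n = n,
    residuals = stats::residuals(fit), fitted = stats::fitted(fit),
    lm = fit), class = "subset_fit")
}

#' Predict the outcome from a fitted linear model
#'
#' Evaluates intercept + sum(beta_i x_i) for new records; every fitted
#' variable must be supplied.
#'
#' @param fit A `subset_fit`.
#' @param newdata Data frame (or named list/vector) with the fit variables.
#' @return Numeric vector of predictions (percent EWL when the fit is an
#'   EWL model).
#' @export
predict_linear <- function(fit, newdata) {
  stopifnot(inherits(fit, "subset_fit"))
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(fit$variables, names(newdata))
  if (length(missing))
    stop("missing variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  M <- as.matrix(as.data.frame(newdata)[fit$variables])
  drop(fit$coefficients[1] + M %*% fit$coefficients[fit$variables])
}

# R2 and model stats of every subset via covariance algebra; C is the
# covariance matrix of the candidates, cv their covariances with y.
subset_stats_ <- function(idx, C, cv, vy, n) {
  k <- length(idx)
  b <- solve(C[idx, idx, drop = FALSE], cv[idx])
  r2 <- drop(crossprod(cv[idx], b)) / vy
  r2 <- min(max(r2, 0), 1)
  df2 <- n - k - 1
  f <- (r2 / k) / ((1 - r2) / df2)
  p <- stats::pf(f, k, df2, lower.tail = FALSE)
  resid_sd <- sqrt((1 - r2) * vy * (n - 1) / df2)
  c(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / df2,
    resid_sd = resid_sd, f = f, p = p)
}

#' Exhaustive best-subset regression search
#'
#' Enumerates every subset of 1..`max_size` candidate predictors, fits
#' each by least squares (on sufficient statistics for speed), discards
#' models whose overall p-value is >= `alpha`, and ranks the rest by R2
#' (descending) with ties broken by smaller residual SD, then fewer
#' variables, then lexicographic variable names.  The top-ranked model is
#' refit with [fit_ols()] for full inference.
#'
#' @param candidates Named numeric matrix or data frame of candidate
#'   predictors.
#' @param y Outcome vector.
#' @param max_size Largest subset size considered (default 4, the cap a
#'   172-record data set supports under the records-per-variable rule of
#'   thumb).
#' @param alpha Overall model p-value threshold (default 0.05).
#' @return List with `table` (one row per enumerated subset: variables,
#'   size, r2, adj_r2, resid_sd, f, p, passes) sorted by rank, and
#'   `selected` (a `subset_fit`, or NULL if no subset passes — flagged,
#'   not fatal).
#' @export
best_subset_search <- function(candidates, y, max_size = 4, alpha = 0.05) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) stop("candidates must be named", call. = FALSE)
  ord <- order(colnames(X))          # candidate-order invariance
  X <- X[, ord, drop = FALSE]
  if (max_size < 1) stop("`max_size` must be >= 1", call. = FALSE)
  max_size <- min(max_size, ncol(X))
  n <- length(y)
  C <- stats::cov(X)
  cv <- drop(stats::cov(X, y))
  vy <- stats::var(y)
  rows <- list()
  for (k in seq_len(max_size)) {
    combs <- utils::combn(ncol(X), k)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      st <- tryCatch(subset_stats_(idx, C, cv, vy, n),
                     error = function(e) NULL)
      if (is.null(st)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variables = paste(colnames(X)[idx], collapse = "+"),
        size = k, r2 = st[["r2"]], adj_r2 = st[["adj_r2"]],
        resid_sd = st[["resid_sd"]], f = st[["f"]], p = st[["p"]])
    }
  }
  tab <- do.call(rbind, rows)
  tab$passes <- tab$p < alpha
  tab <- tab[order(-tab$r2, tab$resid_sd, tab$size, tab$variables), ]
  rownames(tab) <- NULL
  passing <- tab[tab$passes, ]
  selected <- NULL
  if (nrow(passing) > 0) {
    vars <- strsplit(passing$variables[1], "+", fixed = TRUE)[[1]]
    selected <- fit_ols(X[, vars, drop = FALSE], y)
  }
  list(table = tab, selected = selected)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R2_j), R2_j from regressing predictor j on the others;
#' computed here as the diagonal of the inverse correlation matrix.
#' Perfectly collinear designs yield `Inf` with a warning flag.
#'
#' @param X Predictor matrix with >= 2 columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
collinearity_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 columns", call. = FALSE)
  R <- stats::cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(v) || any(v < 0) || any(!is.finite(v))) {
    warning("perfect collinearity: infinite VIF", call. = FALSE)
    v <- rep(Inf, ncol(X))
  }
  stats::setNames(pmax(v, 1), colnames(X))
}

#' Partial correlations of each predictor with the outcome
#'
#' Correlation between the residuals of y and of x_j after both are
#' regressed on the remaining predictors; computed via the identity
#' \eqn{r = t_j / \sqrt{t_j^2 + df}} from the full-model t statistics.
#'
#' @param X Predictor matrix.
#' @param y Outcome vector.
#' @return Named numeric vector of partial correlations.
#' @export
partial_correlations <- function(X, y) {
  X <- as.matrix(X)
  fit <- fit_ols(X, y)
  df <- fit$n - ncol(X) - 1
  t <- fit$t[-1]
  stats::setNames(t / sqrt(t^2 + df), fit$variables)
}

# Jarque-Bera normality test: JB = n/6 (S^2 + (K-3)^2/4) ~ chisq(2)
jarque_bera_ <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  s2 <- mean(m^2)
  S <- mean(m^3) / s2^1.5
  K <- mean(m^4) / s2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, 2, lower.tail = FALSE))
}

# Wald-Wolfowitz runs test on the signs of x (in given order), normal
# approximation; zero values are dropped.
runs_test_ <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(statistic = NA_real_, p.value = NA_real_))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(statistic = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Residual and collinearity diagnostics of a fitted model
#'
#' Reports the diagnostics used to validate the regression model:
#' per-variable VIF, partial and zero-order correlations, residual mean,
#' and residual tests — Jarque-Bera and Lilliefors for normality, a runs
#' test on residual signs (in input order) for independence.
#'
#' @param fit A `subset_fit`.
#' @param X The predictor matrix the model was fit on.
#' @param y The outcome vector.
#' @return List of class `fit_diagnostics`: `vif`, `partial_correlation`,
#'   `zero_order_correlation`, `residual_mean`, `jarque_bera_p`,
#'   `lilliefors_p`, `runs_p`.  With fewer than 8 residuals the asymptotic
#'   tests are flagged and their p-values omitted (`NA`).
#' @export
residual_diagnostics <- function(fit, X, y) {
  stopifnot(inherits(fit, "subset_fit"))
  X <- as.matrix(X)
  r <- fit$residuals
  small <- length(r) < 8
  structure(list(
    vif = if (ncol(X) >= 2) collinearity_vif(X) else
      stats::setNames(1, colnames(X)),
    partial_correlation = partial_correlations(X, y),
    zero_order_correlation = drop(stats::cor(X, y))[seq_len(ncol(X))] |>
      stats::setNames(colnames(X)),
    residual_mean = mean(r),
    jarque_bera_p = if (small) NA_real_ else jarque_bera_(r)$p.value,
    lilliefors_p = if (small) NA_real_ else
      nortest::lillie.test(r)$p.value,
    runs_p = if (small) NA_real_ else runs_test_(r)$p.value,
    small_sample = small), class = "fit_diagnostics")
}

#' Benchmark model with all two-way interactions
#'
#' Builds a design of the standardized main effects plus all pairwise
#' products of standardized mains and fits it by [fit_ols()].  Used as the
#' intermediate benchmark between the linear and the neural model.
#'
#' @param X Main-effect matrix (>= 2 columns).
#' @param y Outcome vector.
#' @return A `subset_fit` on the expanded design (width p + choose(p, 2)).
#' @export
fit_interactions <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need >= 2 main effects", call. = FALSE)
  Z <- standardize(X)$values
  pairs <- utils::combn(p, 2)
  inter <- matrix(NA_real_, nrow(Z), ncol(pairs))
  cn <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    inter[, j] <- Z[, pairs[1, j]] * Z[, pairs[2, j]]
    cn[j] <- paste0(colnames(Z)[pairs[1, j]], ":", colnames(Z)[pairs[2, j]])
  }
  colnames(inter) <- cn
  fit_ols(cbind(Z, inter), y)
}

#' Main effects significantly correlated with the outcome
#'
#' Convenience selector for the interaction benchmark: returns the
#' candidate columns whose zero-order Pearson correlation with y has
#' p < `alpha`.
#'
#' @param candidates Named predictor matrix/data frame.
#' @param y Outcome vector.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Character vector of column names.
#' @export
significant_main_effects <- function(candidates, y, alpha = 0.05) {
  X <- as.matrix(candidates)
  pvals <- vapply(seq_len(ncol(X)), function(j)
    stats::cor.test(X[, j], y)$p.value, numeric(1))
  colnames(X)[pvals < alpha]
}
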