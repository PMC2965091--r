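# round half-up to `digits` decimals (reporting convention for percents)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Binary classifier metrics from a 2x2 confusion
#'
#' Positive group = patients with EWL above the first quartile.  Returns
#' prevalence, sensitivity, false-negative rate, specificity,
#' false-positive rate, accuracy and mis-classification rate, both as raw
#' fractions and as percentages rounded half-up to one decimal.
#'
#' @param tp,fp,tn,fn Non-negative counts (true/false positive/negative).
#' @return List with `counts`, `fractions`, `percent`.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with positive total", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("empty actual class: metrics undefined", call. = FALSE)
  total <- sum(counts)
  fr <- c(prevalence = (tp + fn) / total,
          sensitivity = tp / (tp + fn),
          false_negative_rate = fn / (tp + fn),
          specificity = tn / (tn + fp),
          false_positive_rate = fp / (tn + fp),
          accuracy = (tp + tn) / total)
  fr <- c(fr, mis_classification_rate = unname(1 - fr["accuracy"]))
  list(counts = counts, fractions = fr,
       percent = round_half_up(100 * fr, 1))
}

#' ROC curve with trapezoidal AUC and Hanley-McNeil standard error
#'
#' Sweeps every distinct score as a cutoff (prediction positive when
#' score > cutoff), computes the true/false positive fractions, the
#' trapezoidal area under the curve (equal to the tie-corrected
#' Mann-Whitney statistic), its Hanley-McNeil asymptotic standard error,
#' and the closest-to-corner best cutoff.
#'
#' @param scores Numeric predictive scores (larger = more positive).
#' @param labels Logical or 0/1 vector; TRUE/1 = positive class.
#' @return Object of class `roc_curve`: `thresholds`, `tpf`, `fpf`,
#'   `auc`, `auc_se`, `best_cutoff`, `best_confusion` (counts at the best
#'   cutoff).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpf <- vapply(thr, function(c) sum(scores > c & labels) / n_pos,
                numeric(1))
  fpf <- vapply(thr, function(c) sum(scores > c & !labels) / n_neg,
                numeric(1))
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                    (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  curve <- structure(list(thresholds = thr, tpf = tpf, fpf = fpf,
                          auc = auc, auc_se = auc_se),
                     class = "roc_curve")
  curve$best_cutoff <- best_cutoff(curve)
  pred <- scores > curve$best_cutoff
  curve$best_confusion <- c(tp = sum(pred & labels),
                            fp = sum(pred & !labels),
                            tn = sum(!pred & !labels),
                            fn = sum(!pred & labels))
  curve
}

#' Best ROC cutoff: closest point to the upper-left corner
#'
#' Minimizes the Euclidean distance sqrt((1 - TPF)^2 + FPF^2); ties are
#' broken toward the higher-sensitivity point.
#'
#' @param roc A `roc_curve`.
#' @return The cutoff score value.
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  d <- sqrt((1 - roc$tpf)^2 + roc$fpf^2)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.max(roc$tpf[best])]
  roc$thresholds[best]
}

#' 4x4 quartile confusion matrix
#'
#' Assigns predicted scores and actual EWL independently to quartiles
#' (each by its own thresholds unless given) and cross-tabulates: rows =
#' actual quartile, columns = predicted quartile; column percentages sum
#' to 100 within each predicted quartile.
#'
#' @param predicted Numeric predicted scores.
#' @param actual Numeric actual EWL.
#' @param thresholds_predicted,thresholds_actual Optional
#'   [quartile_thresholds()] (e.g. training-fold thresholds in CV);
#'   computed from the vectors themselves when NULL.
#' @return Object of class `quartile_confusion`: `counts` (4x4),
#'   `column_percent` (4x4), `n`.
#' @export
quartile_confusion <- function(predicted, actual,
                               thresholds_predicted = NULL,
                               thresholds_actual = NULL) {
  if (length(predicted) != length(actual) || length(actual) < 8)
    stop("need equal-length vectors with >= 8 records", call. = FALSE)
  if (is.null(thresholds_predicted)) {
    if (stats::sd(predicted) == 0)
      stop("degenerate (constant) predicted scores", call. = FALSE)
    thresholds_predicted <- quartile_thresholds(predicted)
  }
  if (is.null(thresholds_actual))
    thresholds_actual <- quartile_thresholds(actual)
  qp <- assign_quartile(predicted, thresholds_predicted)
  qa <- assign_quartile(actual, thresholds_actual)
  counts <- table(factor(qa, 1:4), factor(qp, 1:4))
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(actual = 1:4, predicted = 1:4))
  colsum <- colSums(counts)
  pct <- sweep(counts, 2, ifelse(colsum == 0, NA, colsum), "/") * 100
  structure(list(counts = counts, column_percent = pct,
                 n = length(actual)),
            class = "quartile_confusion")
}

#' Centroids of the extreme predicted quartiles
#'
#' Mean actual EWL among records whose predicted score falls in the first
#' and in the fourth predicted quartile; the gap between the two measures
#' how well the model separates poor from good responders.
#'
#' @param predicted,actual As in [quartile_confusion()].
#' @return Named numeric `c(q1 = , q4 = )` in actual-EWL percent.
#' @export
centroid_gap <- function(predicted, actual) {
  thr <- quartile_thresholds(predicted)
  q <- assign_quartile(predicted, thr)
  if (!any(q == 1) || !any(q == 4))
    stop("empty extreme quartile: centroid undefined", call. = FALSE)
  c(q1 = mean(actual[q == 1]), q4 = mean(actual[q == 4]))
}

# ---- cross-validation model specs ------------------------------------

#' Model specifications for cross-validation
#'
#' A CV model spec is a list with functions `fit(train)` and
#' `predict(fitted, test)` operating on cohort data frames.
#' `cv_model_linear` refits the given subset by OLS on each training
#' fold; `cv_model_nlcca` retrains the dual-MLP model (standardizing with
#' training-fold parameters); `cv_model_oracle` predicts the actual EWL
#' exactly and `cv_model_null` returns pure-noise scores — the two
#' boundary cases used to validate the CV machinery.
#'
#' @param variables Predictor column names.
#' @param ... For `cv_model_nlcca`: passed to [train_multistart()].
#' @return A `cv_model` list.
#' @export
cv_model_linear <- function(variables) {
  structure(list(
    label = "linear",
    fit = function(train) fit_ols(train[variables], train$ewl),
    predict = function(fitted, test) predict_linear(fitted, test)),
    class = "cv_model")
}

#' @rdname cv_model_linear
#' @export
cv_model_nlcca <- function(variables, ...) {
  structure(list(
    label = "nlcca",
    fit = function(train) fit_nlcca(train, variables,
                                    allow_unaccepted = TRUE, ...),
    predict = function(fitted, test) predict_nlcca(fitted, test)),
    class = "cv_model")
}

#' @rdname cv_model_linear
#' @export
cv_model_oracle <- function() {
  structure(list(
    label = "oracle",
    fit = function(train) NULL,
    predict = function(fitted, test) test$ewl),
    class = "cv_model")
}

#' @rdname cv_model_linear
#' @export
cv_model_null <- function() {
  structure(list(
    label = "null",
    fit = function(train) NULL,
    predict = function(fitted, test) stats::runif(nrow(test))),
    class = "cv_model")
}

#' Repeated k-fold cross-validation with averaged confusion matrices
#'
#' Per repeat: the cohort is split into k random near-equal folds
#' (optionally stratified by actual-EWL quartile); each fold is held out
#' once while the model is fit on the remainder; quartile thresholds for
#' the actual EWL and for the predicted scores are computed on the
#' training folds only and applied to the held-out fold; pooled test
#' predictions give one 4x4 column-percentage confusion matrix.  Mean and
#' SEM over repeats summarize prediction value.
#'
#' @param cohort A `cohort_table` with `ewl`.
#' @param model A `cv_model` (see [cv_model_linear()]).
#' @param k Number of folds (default 3).
#' @param repeats Number of repeats (default 100).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @param stratify Stratify folds by actual-EWL quartile (default FALSE:
#'   simple random thirds).
#' @return Object of class `cv_result`: `mean_percent`, `sem_percent`
#'   (4x4), `n_repeats`, `k`, `seed`.
#' @export
cross_validate <- function(cohort, model, k = 3, repeats = 100, seed = 1L,
                           stratify = FALSE) {
  stopifnot(inherits(model, "cv_model"))
  n <- nrow(cohort)
  if (n < 3 * k) stop("need n >= 3k records", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  mats <- array(NA_real_, c(4, 4, repeats))
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold <- if (stratify) {
      qa <- assign_quartile(cohort$ewl, quartile_thresholds(cohort$ewl))
      f <- integer(n)
      for (q in 1:4) {
        idx <- which(qa == q)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(k), n))
    }
    pred <- numeric(n); qpred <- integer(n); qact <- integer(n)
    for (fd in seq_len(k)) {
      test_idx <- which(fold == fd)
      train <- cohort[-test_idx, , drop = FALSE]
      test <- cohort[test_idx, , drop = FALSE]
      if (nrow(test) < 2 || nrow(train) < 8)
        stop("fold too small for the model", call. = FALSE)
      fitted <- model$fit(train)
      pr_train <- model$predict(fitted, train)
      pr_test <- model$predict(fitted, test)
      thr_p <- quartile_thresholds(pr_train)
      thr_a <- quartile_thresholds(train$ewl)
      qpred[test_idx] <- assign_quartile(pr_test, thr_p)
      qact[test_idx] <- assign_quartile(test$ewl, thr_a)
    }
    counts <- table(factor(qact, 1:4), factor(qpred, 1:4))
    counts <- matrix(as.numeric(counts), 4, 4)
    colsum <- colSums(counts)
    mats[, , r] <- sweep(counts, 2, ifelse(colsum == 0, NA, colsum),
                         "/") * 100
  }
  mean_m <- apply(mats, c(1, 2), mean, na.rm = TRUE)
  sem_m <- apply(mats, c(1, 2), function(x)
    stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
  dimnames(mean_m) <- dimnames(sem_m) <- list(actual = 1:4, predicted = 1:4)
  structure(list(mean_percent = mean_m, sem_percent = sem_m,
                 n_repeats = repeats, k = k, seed = seed),
            class = "cv_result")
}

#' Aggregate CV prediction value below/above the median
#'
#' Sums the mean confusion percentages over actual quartiles {1,2}
#' (below the median EWL) or {3,4} (above) within one predicted-quartile
#' column — e.g. the share of patients predicted in the 1st quartile who
#' actually achieved an EWL below the median.
#'
#' @param cv A `cv_result`.
#' @param predicted_quartile Column 1..4.
#' @param side "below" or "above".
#' @return Percent (scalar).
#' @export
aggregate_below_above_median <- function(cv, predicted_quartile,
                                         side = c("below", "above")) {
  stopifnot(inherits(cv, "cv_result"))
  side <- match.arg(side)
  rows <- if (side == "below") 1:2 else 3:4
  sum(cv$mean_percent[rows, predicted_quartile])
}
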