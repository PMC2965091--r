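#!/usr/bin/env Rscript
# Stage 5 — repeated 3-fold cross-validation of both models.
#
# Per repeat, the cohort is split into three random folds; each model is
# refit on two folds (standardization and quartile thresholds from the
# training folds only) and predicts the held-out fold; pooled predictions
# give a 4x4 column-percentage confusion matrix.  The linear model uses
# 100 repeats; the dual-MLP uses 30 repeats with a 20-restart budget per
# fold to keep the stage to a few minutes.  Mean +- SEM matrices and the
# below/above-median aggregates for the extreme predicted quartiles are
# reported.

suppressPackageStartupMessages(library(ewlpredict))
cohort <- read_cohort("results/cohort.csv")
sel <- read.csv("results/linear_coefficients.csv")
vars <- setdiff(sel$term, "(Intercept)")

cv_lin <- cross_validate(cohort, cv_model_linear(vars), k = 3,
                         repeats = 100, seed = 20260501)
cv_non <- cross_validate(cohort,
                         cv_model_nlcca(vars, n_hidden = 4, n_runs = 20,
                                        seed = 20260502),
                         k = 3, repeats = 30, seed = 20260501)

report <- function(cv, label) {
  cat("\n", label, " model: CV mean confusion (column %, rows = actual Q1..Q4):\n",
      sep = "")
  print(round(cv$mean_percent, 1))
  cat("SEM:\n"); print(round(cv$sem_percent, 2))
  below1 <- aggregate_below_above_median(cv, 1, "below")
  above4 <- aggregate_below_above_median(cv, 4, "above")
  cat(sprintf("predicted-Q1 patients with actual EWL below the median: %.0f%%\n",
              below1))
  cat(sprintf("predicted-Q4 patients with actual EWL above the median: %.0f%%\n",
              above4))
  invisible(c(below1, above4))
}
a <- report(cv_lin, "linear")
b <- report(cv_non, "nonlinear")

jsonlite::write_json(
  list(linear = list(mean_percent = cv_lin$mean_percent,
                     sem_percent = cv_lin$sem_percent,
                     n_repeats = cv_lin$n_repeats,
                     q1_below_median = a[1], q4_above_median = a[2]),
       nonlinear = list(mean_percent = cv_non$mean_percent,
                        sem_percent = cv_non$sem_percent,
                        n_repeats = cv_non$n_repeats,
                        q1_below_median = b[1], q4_above_median = b[2])),
  "results/cv_results.json", digits = NA)
cat("\nwrote results/cv_results.json\n")
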