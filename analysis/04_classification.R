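#!/usr/bin/env Rscript
# Stage 4 — quartile classification and ROC analysis of both models.
#
# Cross-tabulates predicted-score quartiles against actual-EWL quartiles
# (all-data confusion matrices), computes first/fourth-quartile centroids,
# and sweeps ROC curves for the binary task "EWL above the first
# quartile", reporting AUC with its Hanley-McNeil standard error and the
# closest-to-corner cutoff with the 2x2 metrics at that cutoff.

suppressPackageStartupMessages(library(ewlpredict))
cohort <- read_cohort("results/cohort.csv")
sel <- read.csv("results/linear_coefficients.csv")
vars <- setdiff(sel$term, "(Intercept)")
lin_fit <- fit_ols(cohort[vars], cohort$ewl)
u <- read.csv("results/nlcca_scores.csv")$u

pred <- list(linear = lin_fit$fitted, nonlinear = u)
labels <- cohort$ewl > quartile_thresholds(cohort$ewl)[["q1"]]

roc_rows <- list(); conf_rows <- list()
for (m in names(pred)) {
  qc <- quartile_confusion(pred[[m]], cohort$ewl)
  cat("\n", m, "model: all-data quartile confusion (column %):\n", sep = "")
  print(round(qc$column_percent, 1))
  ct <- centroid_gap(pred[[m]], cohort$ewl)
  cat(sprintf("centroids (actual EWL): predicted-Q1 %.1f%%, predicted-Q4 %.1f%% (gap %.1f)\n",
              ct["q1"], ct["q4"], ct["q4"] - ct["q1"]))
  rc <- roc_curve(pred[[m]], labels)
  bm <- binary_metrics(rc$best_confusion["tp"], rc$best_confusion["fp"],
                       rc$best_confusion["tn"], rc$best_confusion["fn"])
  cat(sprintf("AUC %.3f (SE %.3f); best cutoff %.3f -> sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              rc$auc, rc$auc_se, rc$best_cutoff,
              bm$percent["sensitivity"], bm$percent["specificity"],
              bm$percent["accuracy"]))
  roc_rows[[m]] <- data.frame(model = m, auc = rc$auc, auc_se = rc$auc_se,
                              cutoff = rc$best_cutoff, t(rc$best_confusion),
                              t(bm$percent))
  conf_rows[[m]] <- data.frame(model = m, actual_q = rep(1:4, 4),
                               predicted_q = rep(1:4, each = 4),
                               count = as.vector(qc$counts),
                               column_pct = as.vector(qc$column_percent))
}
write.csv(do.call(rbind, roc_rows), "results/roc_analysis.csv",
          row.names = FALSE)
write.csv(do.call(rbind, conf_rows), "results/alldata_confusions.csv",
          row.names = FALSE)
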