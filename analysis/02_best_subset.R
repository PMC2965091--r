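#!/usr/bin/env Rscript
# Stage 2 — best-subset linear model of EWL.
#
# Enumerates all predictor subsets of size 1-4 drawn from age, BMI and the
# 28 MMPI-2 scales, keeps models with overall p < 0.05, ranks by R2 and
# refits the winner with full inference and diagnostics (VIF, partial
# correlations, residual normality/independence tests), then fits the
# all-two-way-interactions benchmark over the significantly correlated
# main effects.

suppressPackageStartupMessages(library(ewlpredict))
cohort <- read_cohort("results/cohort.csv")

cands <- c("age", "bmi_pre", unlist(mmpi2_scale_families()))
search <- best_subset_search(cohort[cands], cohort$ewl, max_size = 4)
write.csv(head(search$table, 100), "results/subset_search.csv",
          row.names = FALSE)

fit <- search$selected
cat("Selected model:", paste(fit$variables, collapse = " + "), "\n")
cat(sprintf("R = %.3f, R2 = %.3f, adj R2 = %.3f, residual SD = %.2f, F = %.2f, p = %.3g\n",
            sqrt(fit$r2), fit$r2, fit$adj_r2, fit$resid_sd, fit$f,
            fit$model_p))

coef_tab <- data.frame(term = names(fit$coefficients),
                       b = fit$coefficients,
                       se = fit$se, t = fit$t, p = fit$p,
                       beta = c(NA, fit$std_coefficients))
write.csv(coef_tab, "results/linear_coefficients.csv", row.names = FALSE)
print(coef_tab, digits = 3)

diag <- residual_diagnostics(fit, cohort[fit$variables], cohort$ewl)
cat(sprintf("VIF: %s (all < 5: %s)\n",
            paste(sprintf("%s %.2f", names(diag$vif), diag$vif),
                  collapse = ", "),
            all(diag$vif < 5)))
cat(sprintf("Residuals: mean %.2e; Jarque-Bera p = %.2f, Lilliefors p = %.2f, runs test p = %.2f\n",
            diag$residual_mean, diag$jarque_bera_p, diag$lilliefors_p,
            diag$runs_p))

mains <- significant_main_effects(cohort[cands], cohort$ewl)
cat("Main effects significantly correlated with EWL:",
    paste(mains, collapse = ", "), "\n")
if (length(mains) >= 2) {
  int_fit <- fit_interactions(cohort[mains], cohort$ewl)
  cat(sprintf("Two-way-interaction benchmark: %d terms, R2 = %.3f\n",
              length(int_fit$variables), int_fit$r2))
  bench <- data.frame(model = c("linear", "interactions"),
                      r2 = c(fit$r2, int_fit$r2))
  write.csv(bench, "results/interaction_benchmark.csv", row.names = FALSE)
}
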