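#!/usr/bin/env Rscript
# Stage 3 — dual-MLP correlation-maximization model.
#
# Standardizes the selected predictors and EWL, then trains the two
# networks (tanh x-net -> score u, identity y-net -> score v) by 200
# random-restart quasi-Newton minimizations of the constrained cost J_m,
# with 20% validation withheld per run and overfitted runs rejected.
# Also reports the hidden-size trace behind the default of 4 units.

suppressPackageStartupMessages(library(ewlpredict))
cohort <- read_cohort("results/cohort.csv")
sel <- read.csv("results/linear_coefficients.csv")
vars <- setdiff(sel$term, "(Intercept)")

fit <- fit_nlcca(cohort, vars, n_hidden = 4, n_runs = 200,
                 validation_fraction = 0.2, seed = 20260301,
                 allow_unaccepted = TRUE)
tr <- fit$model$training
cat("Dual-MLP model on", paste(vars, collapse = " + "), "\n")
cat(sprintf("runs %d, accepted %d, best J_m %.4f\n",
            tr$n_runs, tr$accepted_runs, tr$best_jm))
cat(sprintf("score correlation r = %.3f (train %.3f, validation %.3f), R2 = %.3f\n",
            tr$corr_all, tr$corr_train, tr$corr_val, tr$corr_all^2))

jsonlite::write_json(
  list(variables = vars, n_hidden = fit$model$n_hidden,
       training = tr[c("n_runs", "accepted_runs", "best_jm", "corr_all",
                       "corr_train", "corr_val", "seed")],
       net_x = fit$model$net_x[c("W1", "b1", "w2", "b2")],
       net_y = fit$model$net_y[c("W1", "b1", "w2", "b2")],
       x_params = fit$x_params, y_params = fit$y_params),
  "results/nlcca_model.json", auto_unbox = TRUE, digits = NA)

scores <- data.frame(id = cohort$id, u = fit$u, v = fit$v,
                     ewl = cohort$ewl)
write.csv(scores, "results/nlcca_scores.csv", row.names = FALSE)

# hidden-size trace (smaller run budget per size; the default of 4 units
# is retained for comparability with the linear model's 4 predictors)
sx <- standardize(cohort[vars]); sy <- standardize(cbind(ewl = cohort$ewl))
trace <- select_hidden_size(sx$values, sy$values, candidate_sizes = 1:6,
                            improvement_threshold = 0.01,
                            n_runs = 25, seed = 20260302,
                            allow_unaccepted = TRUE)
write.csv(trace$trace, "results/hidden_size_trace.csv", row.names = FALSE)
cat("hidden-size trace:\n")
print(trace$trace, digits = 3)
cat("diminishing-returns choice:", trace$selected, "unit(s)\n")
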