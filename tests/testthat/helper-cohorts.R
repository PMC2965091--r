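# shared fixtures: small planted cohorts built in code

planted_cohort <- function(n = 500, rho2 = 0.365, mode = "nonlinear",
                           seed = 42L) {
  generate_cohort(cohort_sim_config(
    n_subjects = n, seed = seed,
    outcome = outcome_spec(mode = mode, target_r2 = rho2)))
}

study_vars <- c("age", "Pa", "Asp", "TpA")

# brute-force AUC: concordant / discordant / tied pair counting
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
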