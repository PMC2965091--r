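#' Validate a cohort table
#'
#' Schema and range checks for patient tables: required columns (id, age,
#' height_cm, weight_pre_kg, bmi_pre, and at least one scale column),
#' numeric cells, age >= 18 (the psychometric instrument is designed for
#' adults), T scores within [0, 120], positive heights and weights.
#' Problems are collected into an itemized report before failing.
#'
#' @param table A data frame (e.g. from [read_cohort()]).
#' @param scales Scale columns the table must provide; defaults to the
#'   full MMPI-2 scale set.
#' @return The validated table (class `cohort_table`), invisibly the same
#'   object.  Throws a condition whose message itemizes every violation.
#' @export
validate_input <- function(table,
                           scales = unlist(mmpi2_scale_families())) {
  problems <- character(0)
  required <- c("id", "age", "height_cm", "weight_pre_kg", "bmi_pre")
  miss <- setdiff(required, names(table))
  if (length(miss))
    problems <- c(problems, paste("missing columns:",
                                  paste(miss, collapse = ", ")))
  miss_s <- setdiff(scales, names(table))
  if (length(miss_s))
    problems <- c(problems, paste("missing scale columns:",
                                  paste(miss_s, collapse = ", ")))
  scales <- setdiff(scales, miss_s)
  if (!length(problems)) {
    num_cols <- c("age", "height_cm", "weight_pre_kg", "bmi_pre", scales)
    for (v in num_cols) {
      if (!is.numeric(table[[v]]))
        problems <- c(problems, paste0("non-numeric column: ", v))
    }
    if (anyDuplicated(table$id))
      problems <- c(problems, "duplicate subject identifiers")
    if (is.numeric(table$age) && any(table$age < 18))
      problems <- c(problems,
                    paste0("age below 18 in rows ",
                           paste(which(table$age < 18), collapse = ","),
                           " (instrument designed for adults)"))
    if (is.numeric(table$height_cm) && any(table$height_cm <= 0))
      problems <- c(problems, "non-positive heights")
    for (s in scales) {
      if (is.numeric(table[[s]]) &&
          any(table[[s]] < 0 | table[[s]] > 120))
        problems <- c(problems, paste0("T scores outside [0, 120] in ", s))
    }
  }
  if (length(problems))
    stop("input validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  class(table) <- unique(c("cohort_table", class(table)))
  invisible(table)
}

#' Pipeline configuration
#'
#' Collects every knob of the full analysis.  Exactly one of `input_path`
#' (an existing cohort CSV) or `sim_config` (a [cohort_sim_config()])
#' must be given.
#'
#' @param input_path Path to a cohort CSV, or NULL.
#' @param sim_config A [cohort_sim_config()], or NULL.
#' @param candidates Candidate predictor columns for subset selection
#'   (default: age, bmi_pre and all scales).
#' @param max_subset_size Best-subset cap (default 4).
#' @param n_hidden,n_runs,validation_fraction,penalty_weight Dual-MLP
#'   settings.
#' @param cv_k,cv_repeats Cross-validation folds and repeats.
#' @param seed Master seed; stage seeds are derived as seed + fixed
#'   offsets so any stage reproduces in isolation.
#' @param outdir Output directory for artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, sim_config = NULL,
                            candidates = NULL, max_subset_size = 4,
                            n_hidden = 4, n_runs = 200,
                            validation_fraction = 0.2, penalty_weight = 1,
                            cv_k = 3, cv_repeats = 100,
                            seed = 1L, outdir = tempfile("ewl_run_")) {
  if (is.null(input_path) == is.null(sim_config))
    stop("exactly one of `input_path` / `sim_config` must be given",
         call. = FALSE)
  structure(list(input_path = input_path, sim_config = sim_config,
                 candidates = candidates,
                 max_subset_size = max_subset_size, n_hidden = n_hidden,
                 n_runs = n_runs, validation_fraction = validation_fraction,
                 penalty_weight = penalty_weight, cv_k = cv_k,
                 cv_repeats = cv_repeats, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — cohort (simulate or load), normative
#' scale comparison, best-subset selection, linear fit with diagnostics,
#' two-way-interaction benchmark, dual-MLP training, quartile/ROC
#' evaluation of both models, and repeated cross-validation — writing
#' per-stage artifacts (CSV/JSON) under `config$outdir`.  Re-running with
#' the same config reproduces every output.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`cohort`,
#'   `normative`, `selection`, `linear_fit`, `diagnostics`,
#'   `interaction_fit`, `nlcca_fit`, `evaluation`, `cv_linear`,
#'   `cv_nlcca`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  # stage 1: cohort
  cohort <- if (!is.null(config$sim_config)) {
    generate_cohort(config$sim_config)
  } else {
    read_cohort(config$input_path)
  }
  if (nrow(cohort) < 8)
    stop("selection stage: insufficient data (need >= 8 records)",
         call. = FALSE)
  write_cohort(cohort, file.path(config$outdir, "cohort.csv"))
  out$cohort <- cohort

  # stage 2: cohort vs normative population
  out$normative <- compare_scales_to_normative(cohort)
  utils::write.csv(out$normative,
                   file.path(config$outdir, "normative_comparison.csv"),
                   row.names = FALSE)

  # stage 3: best-subset selection
  candidates <- config$candidates
  if (is.null(candidates))
    candidates <- c("age", "bmi_pre",
                    intersect(unlist(mmpi2_scale_families()), names(cohort)))
  sel <- best_subset_search(cohort[candidates], cohort$ewl,
                            max_size = config$max_subset_size)
  utils::write.csv(utils::head(sel$table, 50),
                   file.path(config$outdir, "subset_search.csv"),
                   row.names = FALSE)
  if (is.null(sel$selected))
    stop("selection stage: no subset reached p < 0.05", call. = FALSE)
  out$selection <- sel
  vars <- sel$selected$variables

  # stage 4: linear model + diagnostics
  out$linear_fit <- sel$selected
  out$diagnostics <- residual_diagnostics(sel$selected,
                                          cohort[vars], cohort$ewl)
  jsonlite::write_json(
    list(variables = vars,
         coefficients = as.list(sel$selected$coefficients),
         r2 = sel$selected$r2, adj_r2 = sel$selected$adj_r2,
         resid_sd = sel$selected$resid_sd, f = sel$selected$f,
         model_p = sel$selected$model_p,
         vif = as.list(out$diagnostics$vif),
         partial_correlation = as.list(out$diagnostics$partial_correlation)),
    file.path(config$outdir, "linear_fit.json"),
    auto_unbox = TRUE, digits = NA)

  # stage 5: interaction benchmark over significantly correlated mains
  mains <- significant_main_effects(cohort[candidates], cohort$ewl)
  out$interaction_fit <- if (length(mains) >= 2)
    fit_interactions(cohort[mains], cohort$ewl) else NULL

  # stage 6: dual-MLP model
  out$nlcca_fit <- fit_nlcca(cohort, vars, allow_unaccepted = TRUE,
                             n_hidden = config$n_hidden,
                             n_runs = config$n_runs,
                             validation_fraction = config$validation_fraction,
                             penalty_weight = config$penalty_weight,
                             seed = config$seed + 1000L)
  tr <- out$nlcca_fit$model$training
  jsonlite::write_json(
    list(variables = vars, n_hidden = config$n_hidden,
         n_runs = tr$n_runs, accepted_runs = tr$accepted_runs,
         best_jm = tr$best_jm, corr_all = tr$corr_all,
         corr_train = tr$corr_train, corr_val = tr$corr_val,
         net_x = out$nlcca_fit$model$net_x[c("W1", "b1", "w2", "b2")],
         net_y = out$nlcca_fit$model$net_y[c("W1", "b1", "w2", "b2")],
         x_params = out$nlcca_fit$x_params,
         y_params = out$nlcca_fit$y_params),
    file.path(config$outdir, "nlcca_model.json"),
    auto_unbox = TRUE, digits = NA)

  # stage 7: quartile + ROC evaluation of both models
  labels <- cohort$ewl > quartile_thresholds(cohort$ewl)[["q1"]]
  pred_lin <- predict_linear(sel$selected, cohort)
  u <- out$nlcca_fit$u
  out$evaluation <- list(
    linear = list(confusion = quartile_confusion(pred_lin, cohort$ewl),
                  roc = roc_curve(pred_lin, labels),
                  centroids = centroid_gap(pred_lin, cohort$ewl)),
    nlcca = list(confusion = quartile_confusion(u, cohort$ewl),
                 roc = roc_curve(u, labels),
                 centroids = centroid_gap(u, cohort$ewl)))
  roc_tab <- do.call(rbind, lapply(c("linear", "nlcca"), function(m) {
    rc <- out$evaluation[[m]]$roc
    data.frame(model = m, auc = rc$auc, auc_se = rc$auc_se,
               best_cutoff = rc$best_cutoff,
               t(rc$best_confusion))
  }))
  utils::write.csv(roc_tab, file.path(config$outdir, "roc.csv"),
                   row.names = FALSE)

  # stage 8: repeated cross-validation (linear + nlcca)
  out$cv_linear <- cross_validate(cohort, cv_model_linear(vars),
                                  k = config$cv_k,
                                  repeats = config$cv_repeats,
                                  seed = config$seed + 2000L)
  out$cv_nlcca <- cross_validate(
    cohort,
    cv_model_nlcca(vars, n_hidden = config$n_hidden,
                   n_runs = max(5L, config$n_runs %/% 10L),
                   validation_fraction = config$validation_fraction,
                   penalty_weight = config$penalty_weight,
                   seed = config$seed + 3000L),
    k = config$cv_k, repeats = config$cv_repeats,
    seed = config$seed + 2000L)
  jsonlite::write_json(
    lapply(list(linear = out$cv_linear, nlcca = out$cv_nlcca), function(cv)
      list(mean_percent = cv$mean_percent, sem_percent = cv$sem_percent,
           n_repeats = cv$n_repeats, k = cv$k)),
    file.path(config$outdir, "cv_results.json"), digits = NA)

  out$summary <- data.frame(
    model = c("linear", "interactions", "nlcca"),
    r = c(sqrt(sel$selected$r2),
          if (is.null(out$interaction_fit)) NA else
            sqrt(out$interaction_fit$r2),
          tr$corr_all),
    r2 = c(sel$selected$r2,
           if (is.null(out$interaction_fit)) NA else out$interaction_fit$r2,
           tr$corr_all^2),
    auc = c(out$evaluation$linear$roc$auc, NA,
            out$evaluation$nlcca$roc$auc))
  utils::write.csv(out$summary, file.path(config$outdir, "summary.csv"),
                   row.names = FALSE)
  invisible(out)
}
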