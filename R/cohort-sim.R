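#' MMPI-2 scale labels used throughout the package
#'
#' Validity (L, F, K), clinical (Hs..Si) and content (Anx..Trt) scales; the
#' three families matter for the default inter-scale correlation structure.
#'
#' @return Named list of character vectors `validity`, `clinical`,
#'   `content`.
#' @export
mmpi2_scale_families <- function() {
  list(
    validity = c("L", "F", "K"),
    clinical = c("Hs", "D", "Hy", "Pd", "Mf", "Pa", "Pt", "Sc", "Ma", "Si"),
    content  = c("Anx", "Frs", "Obs", "Dep", "Hea", "Biz", "Ang", "Cyn",
                 "Asp", "TpA", "Lse", "Sod", "Fam", "Wrk", "Trt")
  )
}

#' Default exchangeable within-family T-score correlation matrix
#'
#' Scales within the same family (validity / clinical / content) share a
#' common correlation `rho`; scales in different families are uncorrelated.
#' `rho = 0.3` keeps collinearity present but mild (all VIF well below 5),
#' so subset selection is non-trivial without being degenerate.
#'
#' @param scale_names Character vector of scale labels.
#' @param rho Within-family correlation, in [0, 1).
#' @return Correlation matrix with unit diagonal.
#' @export
default_scale_correlation <- function(scale_names = unlist(mmpi2_scale_families()),
                                      rho = 0.3) {
  fam <- mmpi2_scale_families()
  family_of <- function(s) {
    for (f in names(fam)) if (s %in% fam[[f]]) return(f)
    "other"
  }
  families <- vapply(scale_names, family_of, character(1))
  p <- length(scale_names)
  R <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j && families[i] == families[j] && families[i] != "other")
      R[i, j] <- rho
  }
  dimnames(R) <- list(scale_names, scale_names)
  R
}

#' Specification of the planted EWL outcome
#'
#' Describes how percent excess weight loss depends on a weighted index of
#' standardized predictors.  In `mode = "nonlinear"` the index passes
#' through a saturating tanh link before noise is added, giving the
#' monotone nonlinear structure the dual-MLP model is designed to recover;
#' in `mode = "linear"` the link is the identity.  Gaussian noise variance
#' is set so that the squared correlation between the (linked) index and
#' the final EWL equals `target_r2`.
#'
#' Defaults mirror the study cohort: predictors age, Pa, Asp, TpA with
#' relative weights matching the signs and magnitudes of the fitted
#' standardized coefficients (negative for age/Pa/Asp, positive for TpA),
#' EWL mean 48.19 and SD 19.71 percent.
#'
#' @param mode "linear" or "nonlinear".
#' @param predictor_names Character vector of cohort columns driving EWL.
#' @param weights Numeric weights, one per predictor.
#' @param target_r2 Squared correlation between link(index) and EWL, in
#'   [0, 1).
#' @param link_gain Slope of the tanh link in index-SD units (nonlinear
#'   mode only); larger values give stronger saturation.
#' @param ewl_mean,ewl_sd Target EWL moments, percent.
#' @return Object of class `outcome_spec`.
#' @export
outcome_spec <- function(mode = c("nonlinear", "linear"),
                         predictor_names = c("age", "Pa", "Asp", "TpA"),
                         weights = c(-0.148, -0.239, -0.260, 0.182),
                         target_r2 = 0.365,
                         link_gain = 1.5,
                         ewl_mean = 48.19, ewl_sd = 19.71) {
  mode <- match.arg(mode)
  if (length(predictor_names) == 0)
    stop("`predictor_names` must be non-empty", call. = FALSE)
  if (length(weights) != length(predictor_names))
    stop("`weights` must match `predictor_names`", call. = FALSE)
  if (!is.finite(target_r2) || target_r2 < 0 || target_r2 >= 1)
    stop("`target_r2` must lie in [0, 1)", call. = FALSE)
  if (ewl_sd <= 0) stop("`ewl_sd` must be positive", call. = FALSE)
  structure(list(mode = mode, predictor_names = predictor_names,
                 weights = weights, target_r2 = target_r2,
                 link_gain = link_gain, ewl_mean = ewl_mean,
                 ewl_sd = ewl_sd),
            class = "outcome_spec")
}

#' Configuration of the synthetic cohort generator
#'
#' Marginal moments default to the study population: age 41.7 +- 11.3
#' years, pre-surgical BMI 42.5 +- 5.1 kg/m2, T scores 50 +- 10.  Heights
#' (162 +- 6 cm, not reported by the study) exist solely so that the
#' Lorentz/EWL arithmetic round-trips through pre/post weights.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param age_mean,age_sd Age moments, years.
#' @param bmi_mean,bmi_sd Pre-surgical BMI moments, kg/m2.
#' @param height_mean,height_sd Height moments, cm.
#' @param scale_names MMPI-2 scale labels to simulate.
#' @param tscore_mean,tscore_sd Marginal T-score moments.
#' @param scale_correlation Positive semi-definite correlation matrix with
#'   unit diagonal, one row/column per scale.
#' @param outcome An [outcome_spec()] (or NULL to skip outcome planting in
#'   [generate_cohort()]).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 172,
                              age_mean = 41.7, age_sd = 11.3,
                              bmi_mean = 42.5, bmi_sd = 5.1,
                              height_mean = 162, height_sd = 6,
                              scale_names = unlist(mmpi2_scale_families()),
                              tscore_mean = 50, tscore_sd = 10,
                              scale_correlation = default_scale_correlation(scale_names),
                              outcome = outcome_spec(),
                              seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 0 ||
      n_subjects != round(n_subjects))
    stop("`n_subjects` must be a non-negative integer", call. = FALSE)
  for (s in c(age_sd, bmi_sd, height_sd, tscore_sd))
    if (s <= 0) stop("all SDs must be positive", call. = FALSE)
  R <- as.matrix(scale_correlation)
  p <- length(scale_names)
  if (!all(dim(R) == c(p, p)))
    stop("`scale_correlation` must be ", p, "x", p, call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("`scale_correlation` must have unit diagonal", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8)
    stop("`scale_correlation` must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`scale_correlation` must be positive semi-definite", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 scale_names = scale_names,
                 tscore_mean = tscore_mean, tscore_sd = tscore_sd,
                 scale_correlation = R, outcome = outcome,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# normal draws truncated to [lo, hi] by inverse-CDF sampling (vectorized)
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws correlated standard-normal scale deviates (Gaussian copula on
#' `scale_correlation`), maps them affinely to the configured T-score
#' moments, and draws age / height / BMI from truncated normals (age >= 18,
#' height in [140, 190] cm, BMI in [25, 70] kg/m2).  Pre-surgical weight is
#' back-computed from BMI and height.  If `config$outcome` is non-NULL the
#' EWL outcome is planted immediately via [plant_outcome()].
#'
#' @param config A [cohort_sim_config()].
#' @return A data frame of class `cohort_table` with columns `id`, `age`,
#'   `height_cm`, `weight_pre_kg`, `weight_post_kg`, `bmi_pre`, `ewl`, then
#'   one column per scale; attribute `provenance` stores the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_subjects
  p <- length(config$scale_names)
  set.seed(config$seed)
  if (n == 0) {
    scales <- matrix(numeric(0), 0, p, dimnames = list(NULL, config$scale_names))
    out <- data.frame(id = character(0), age = numeric(0),
                      height_cm = numeric(0), weight_pre_kg = numeric(0),
                      weight_post_kg = numeric(0), bmi_pre = numeric(0),
                      ewl = numeric(0))
    out <- cbind(out, as.data.frame(scales))
  } else {
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = config$scale_correlation)
    if (n == 1) Z <- matrix(Z, 1, p)
    scales <- config$tscore_mean + config$tscore_sd * Z
    colnames(scales) <- config$scale_names
    age <- rtruncnorm_(n, config$age_mean, config$age_sd, 18, Inf)
    height <- rtruncnorm_(n, config$height_mean, config$height_sd, 140, 190)
    bmi <- rtruncnorm_(n, config$bmi_mean, config$bmi_sd, 25, 70)
    weight_pre <- bmi * (height / 100)^2
    out <- data.frame(id = sprintf("S%04d", seq_len(n)),
                      age = age, height_cm = height,
                      weight_pre_kg = weight_pre,
                      weight_post_kg = NA_real_, bmi_pre = bmi,
                      ewl = NA_real_)
    out <- cbind(out, as.data.frame(scales))
  }
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- list(config = config, seed = config$seed)
  if (!is.null(config$outcome) && n > 0)
    out <- plant_outcome(out, config$outcome, seed = config$seed + 1L)
  out
}

#' Plant an EWL outcome with known dependence structure
#'
#' Builds the index \eqn{t = \sum_i w_i z_i} over standardized predictors,
#' applies the link (identity, or tanh of the gain-scaled index for
#' nonlinear mode), adds Gaussian noise with variance chosen so that
#' \eqn{cor(link, EWL)^2 = target\_r2}, and affinely maps the result to the
#' requested EWL mean/SD.  Noise is drawn from a per-record truncated
#' normal so every EWL lands in [0, 100] without clipping planted values.
#' Post-surgical weights are back-solved so that recomputing EWL from
#' weights and height reproduces the planted value exactly.
#'
#' @param cohort A `cohort_table`.
#' @param spec An [outcome_spec()].
#' @param seed Integer seed for the noise draw.
#' @return The cohort with `ewl` and `weight_post_kg` filled in; the
#'   attribute `planted` records the spec, the link values and the seed.
#' @export
plant_outcome <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(spec, "outcome_spec"))
  missing <- setdiff(spec$predictor_names, names(cohort))
  if (length(missing))
    stop("predictors absent from cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(cohort)
  if (n < 2) stop("need at least 2 records to plant an outcome", call. = FALSE)
  set.seed(seed)
  Z <- standardize(cohort[spec$predictor_names])$values
  index <- drop(Z %*% spec$weights)
  s <- if (spec$mode == "nonlinear") {
    tanh(spec$link_gain * index / stats::sd(index))
  } else index
  if (spec$target_r2 == 0) {
    ewl <- rtruncnorm_(n, spec$ewl_mean, spec$ewl_sd, 0, 100)
    link <- rep(0, n)
  } else {
    vs <- stats::var(s)
    noise_sd <- sqrt(vs * (1 - spec$target_r2) / spec$target_r2)
    # fixed affine map derived from the theoretical total variance, so the
    # truncation below only perturbs individual noise draws
    a <- spec$ewl_sd / sqrt(vs + noise_sd^2)
    b <- spec$ewl_mean - a * mean(s)
    lo <- (0 - b) / a - s
    hi <- (100 - b) / a - s
    e <- rtruncnorm_(n, 0, noise_sd, lo, hi)
    ewl <- b + a * (s + e)
    link <- s
  }
  cohort$ewl <- ewl
  ideal <- lorentz_ideal_weight(cohort$height_cm)
  excess <- cohort$weight_pre_kg - ideal
  if (any(excess <= 0))
    stop("pre-surgical weight at or below ideal weight: EWL undefined",
         call. = FALSE)
  cohort$weight_post_kg <- cohort$weight_pre_kg - ewl / 100 * excess
  attr(cohort, "planted") <- list(spec = spec, link = link, seed = seed)
  cohort
}

#' Per-variable summary of a cohort
#'
#' @param cohort A `cohort_table` (non-empty).
#' @return Data frame with one row per numeric variable: mean, sd, min,
#'   max.  With a single record the SD is `NA` (flagged undefined).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  stats_df <- do.call(rbind, lapply(num, function(v) {
    x <- cohort[[v]]
    data.frame(variable = v, mean = mean(x),
               sd = if (nrow(cohort) > 1) stats::sd(x) else NA_real_,
               min = min(x), max = max(x))
  }))
  rownames(stats_df) <- NULL
  stats_df
}

#' Write / read a cohort as CSV with a JSON provenance sidecar
#'
#' The CSV has one row per subject with the documented column order (id,
#' age, height_cm, weight_pre_kg, weight_post_kg, bmi_pre, ewl, scales);
#' the sidecar `<path>.json` stores the generating configuration and seed,
#' or `"observed"` for external data.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV file path.
#' @return `write_cohort`: `path`, invisibly.  `read_cohort`: a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  prov <- attr(cohort, "provenance")
  side <- if (is.null(prov)) list(provenance = "observed") else
    list(provenance = "simulated", seed = prov$seed,
         config = prov$config[setdiff(names(prov$config),
                                      c("scale_correlation", "outcome"))])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @param check Validate the table with [validate_input()] after reading.
#' @export
read_cohort <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (check) df <- validate_input(df)
  class(df) <- c("cohort_table", "data.frame")
  df
}
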