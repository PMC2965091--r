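#' Normative T-score class distribution
#'
#' Percent of the normative population in each T-score class (<50, 50-64,
#' 65-74, >=75).  T-score norming makes the distribution identical across
#' scales, so a single four-class column applies to every scale; the
#' packaged values ship in `inst/extdata/normative_tscore_percent.csv`
#' and can be edited there.
#'
#' @return Named numeric percent vector summing to 100.
#' @export
normative_tscore_percent <- function() {
  path <- system.file("extdata", "normative_tscore_percent.csv",
                      package = "ewlpredict")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$percent, df$class)
}

#' T-score class labels
#' @return Character vector of the four class labels.
#' @export
tscore_classes <- function() c("<50", "50-64", "65-74", ">=75")

#' Categorize T scores into the four conventional classes
#'
#' Integer-boundary binning: <50, 50-64, 65-74, >=75.  Scores are rounded
#' half-up to integers first (MMPI-2 T scores are integers by convention;
#' simulated scores are continuous).
#'
#' @param tscores Numeric vector of T scores (finite).
#' @return Named integer vector of counts per class (sums to
#'   `length(tscores)`).
#' @export
categorize_tscores <- function(tscores) {
  if (any(!is.finite(tscores))) stop("T scores must be finite", call. = FALSE)
  t <- floor(tscores + 0.5)
  counts <- c(sum(t < 50), sum(t >= 50 & t <= 64),
              sum(t >= 65 & t <= 74), sum(t >= 75))
  stats::setNames(as.integer(counts), tscore_classes())
}

#' Chi-square goodness of fit against the normative distribution
#'
#' Tests whether observed class counts depart from the normative percent
#' distribution: X2 = sum (obs - exp)^2 / exp with exp = n * p, df =
#' classes - 1.  Cells with expected count < 5 are flagged (the
#' asymptotic approximation weakens there).
#'
#' @param observed Integer counts per class.
#' @param normative_percent Percent per class (defaults to the packaged
#'   normative distribution); must sum to 100.
#' @return List: `statistic`, `df`, `p.value`, `expected`,
#'   `low_expected` (logical per class).
#' @export
chi_square_vs_normative <- function(observed,
                                    normative_percent = normative_tscore_percent()) {
  if (abs(sum(normative_percent) - 100) > 0.01)
    stop("normative percents must sum to 100", call. = FALSE)
  if (any(normative_percent <= 0))
    stop("zero expected count: chi-square undefined", call. = FALSE)
  n <- sum(observed)
  if (n == 0) stop("no observations", call. = FALSE)
  p <- normative_percent / 100
  ht <- suppressWarnings(stats::chisq.test(observed, p = p))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = unname(n * p),
       low_expected = unname(n * p < 5))
}

#' Post-hoc standardized residuals per T-score class
#'
#' Adjusted standardized residual (obs - exp) / sqrt(exp (1 - p)) per
#' class, with two-sided normal-approximation p-values, identifying which
#' classes drive a significant chi-square.
#'
#' @inheritParams chi_square_vs_normative
#' @return Data frame: class, observed, expected, residual, p.value.
#' @export
posthoc_residuals <- function(observed,
                              normative_percent = normative_tscore_percent()) {
  if (any(normative_percent <= 0))
    stop("zero expected count", call. = FALSE)
  n <- sum(observed)
  if (n == 0) stop("no observations", call. = FALSE)
  p <- normative_percent / 100
  expd <- n * p
  res <- (observed - expd) / sqrt(expd * (1 - p))
  data.frame(class = names(normative_percent), observed = as.integer(observed),
             expected = unname(expd), residual = unname(res),
             p.value = unname(2 * stats::pnorm(-abs(res))),
             row.names = NULL)
}

#' Compare every cohort scale against the normative population
#'
#' Categorizes each scale's T scores and runs the chi-square test plus
#' post-hoc residuals, optionally Bonferroni-adjusting the chi-square
#' p-values across scales.
#'
#' @param cohort A `cohort_table`.
#' @param scales Scale column names (default: all MMPI-2 scales present).
#' @param bonferroni Adjust chi-square p-values across scales.
#' @return Data frame: one row per scale with counts, X2, p, and per-class
#'   residual significance flags.
#' @export
compare_scales_to_normative <- function(cohort,
                                        scales = intersect(unlist(mmpi2_scale_families()),
                                                           names(cohort)),
                                        bonferroni = FALSE) {
  rows <- lapply(scales, function(s) {
    counts <- categorize_tscores(cohort[[s]])
    ht <- chi_square_vs_normative(counts)
    ph <- posthoc_residuals(counts)
    data.frame(scale = s,
               n_lt50 = counts[1], n_50_64 = counts[2],
               n_65_74 = counts[3], n_ge75 = counts[4],
               statistic = ht$statistic, p.value = ht$p.value,
               posthoc_sig = paste(tscore_classes()[ph$p.value < 0.05],
                                   collapse = ";"),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p.adjusted <- stats::p.adjust(out$p.value, "bonferroni")
  out
}
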