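#' Ideal body weight by the Lorentz formula (female form)
#'
#' Computes ideal body weight from standing height using the Lorentz
#' formula for women: \eqn{height - 100 - (height - 150)/2}, with height in
#' centimetres and the result in kilograms.  This is the ideal-weight
#' definition that enters the excess-weight-loss (EWL) denominator.
#'
#' @param height_cm Numeric vector of heights in centimetres; must be > 0.
#' @return Numeric vector of ideal weights in kg.
#' @examples
#' lorentz_ideal_weight(c(150, 160, 170))  # 50, 55, 60
#' @export
lorentz_ideal_weight <- function(height_cm) {
  if (!is.numeric(height_cm) || any(!is.finite(height_cm)))
    stop("`height_cm` must be finite numeric", call. = FALSE)
  if (any(height_cm <= 0))
    stop("`height_cm` must be positive", call. = FALSE)
  height_cm - 100 - (height_cm - 150) / 2
}

#' Percent excess weight loss (EWL)
#'
#' EWL is the fraction of excess weight (weight above ideal) lost since
#' surgery, expressed in percent:
#' \deqn{100 (w_{pre} - w_{cur}) / (w_{pre} - w_{ideal}).}
#' It is linear in the current weight, may be negative (weight gain) and may
#' exceed 100 (weight below ideal).
#'
#' @param weight_pre Pre-surgical weight, kg.
#' @param weight_current Current (e.g. 24-month) weight, kg.
#' @param ideal Ideal weight, kg (see [lorentz_ideal_weight()]); must be
#'   strictly below `weight_pre`.
#' @return Percent EWL, same length as the inputs.
#' @export
excess_weight_loss <- function(weight_pre, weight_current, ideal) {
  if (any(!is.finite(weight_pre)) || any(!is.finite(weight_current)) ||
      any(!is.finite(ideal)))
    stop("weights must be finite", call. = FALSE)
  if (any(weight_pre <= ideal))
    stop("`weight_pre` must exceed `ideal`: EWL denominator undefined",
         call. = FALSE)
  100 * (weight_pre - weight_current) / (weight_pre - ideal)
}

#' Column-wise standardization with reusable parameters
#'
#' Centres and scales each column to mean 0 and sample SD 1 (denominator
#' n-1).  When `params` is supplied (e.g. computed on a training fold) the
#' stored means/SDs are applied instead, so test data are mapped with
#' training-fold parameters and no information leaks across folds.
#'
#' @param x Numeric matrix or data frame of numeric columns.
#' @param params Optional list with elements `mean` and `sd` (named numeric
#'   vectors, one entry per column), as returned by a previous call.
#' @return List with `values` (standardized matrix) and `params`.
#' @export
standardize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (is.null(params)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    if (any(!is.finite(sdv)) || any(sdv <= 0))
      stop("degenerate column: zero or undefined SD and no `params` supplied",
           call. = FALSE)
    params <- list(mean = mu, sd = sdv)
  } else {
    if (!all(c("mean", "sd") %in% names(params)))
      stop("`params` must contain `mean` and `sd`", call. = FALSE)
    if (length(params$mean) != ncol(x) || length(params$sd) != ncol(x))
      stop("`params` length does not match columns of `x`", call. = FALSE)
  }
  z <- sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  list(values = z, params = params)
}

#' Empirical quartile thresholds of a numeric vector
#'
#' Returns the 25th, 50th and 75th percentiles under the
#' linear-interpolation quantile rule (R type 7).  These are the "upper
#' thresholds" separating consecutive EWL quartiles.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Object of class `quartile_thresholds`: named numeric
#'   `c(q1=, q2=, q3=)` in ascending order.
#' @export
quartile_thresholds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("need at least 4 values to form quartiles", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75),
                       names = FALSE, type = 7)
  structure(c(q1 = q[1], q2 = q[2], q3 = q[3]),
            class = "quartile_thresholds")
}

#' Assign values to quartiles given thresholds
#'
#' A value equal to a threshold belongs to the lower quartile (the
#' thresholds are upper bounds of quartiles 1-3): quartile 1 if
#' `value <= q1`, 2 if `q1 < value <= q2`, 3 if `q2 < value <= q3`, else 4.
#'
#' @param values Numeric vector.
#' @param thresholds A [quartile_thresholds()] result (or ascending numeric
#'   vector of length 3).
#' @return Integer vector of quartile indices in 1..4.
#' @export
assign_quartile <- function(values, thresholds) {
  t <- unclass(thresholds)
  if (length(t) != 3 || is.unsorted(t))
    stop("`thresholds` must be 3 ascending values", call. = FALSE)
  unname(1L + (values > t[1]) + (values > t[2]) + (values > t[3]))
}
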