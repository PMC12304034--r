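# Polynomial calibration of temperature-sensitive transmitters / PIT tags.
#
# Temperature-sensitive radio transmitters report temperature as a pulse rate
# (or inter-pulse interval); before deployment each transmitter is calibrated
# in a water bath across the working range (typically 5-50 degC) and skin
# temperatures are recovered by evaluating a polynomial regression of bath
# temperature on pulse rate.

#' Fit a polynomial calibration curve
#'
#' Least-squares polynomial regression of bath temperature on the raw
#' transmitter reading (pulse rate or inter-pulse interval). When `degree` is
#' `NULL` the degree is chosen automatically among 2--4 by adjusted R-squared
#' (subject to having at least `degree + 2` points). A warning is emitted if
#' the fit's R-squared does not exceed 0.98, the conventional quality bar for
#' transmitter calibrations.
#'
#' @param points data.frame with numeric columns `pulse_rate` and `bath_temp`
#'   (degC). Bath temperatures are expected inside the calibrated range
#'   (5--50 degC by convention); values outside only generate a warning.
#' @param degree polynomial degree, or `NULL` for automatic selection 2--4.
#' @param x one of `"pulse_rate"` (default) or `"interval"`; with
#'   `"interval"` the predictor is treated as an inter-pulse interval in
#'   seconds. Only recorded as metadata -- the fit is identical.
#' @return object of class `calibration_curve`: a list with `coefficients`
#'   (intercept first), `degree`, `r_squared`, `adj_r_squared`,
#'   `valid_range` (range of calibrated bath temperatures, degC),
#'   `x_range` (range of calibrated pulse rates), `fitted_on`, `x_type`.
#' @examples
#' pts <- data.frame(pulse_rate = seq(20, 70, 10),
#'                   bath_temp = 2 + 0.5 * seq(20, 70, 10))
#' fit_calibration(pts, degree = 2)
#' @export
fit_calibration <- function(points, degree = NULL, x = c("pulse_rate", "interval")) {
  x <- match.arg(x)
  if (!is.data.frame(points) || !all(c("pulse_rate", "bath_temp") %in% names(points)))
    stopf("`points` must be a data.frame with columns pulse_rate and bath_temp")
  pr <- points$pulse_rate
  bt <- points$bath_temp
  if (anyNA(pr) || anyNA(bt)) stopf("calibration points contain missing values")
  dup <- duplicated(pr)
  if (any(dup))
    stopf("duplicate pulse rates in calibration table (rows %s): design is rank-deficient",
          paste(which(pr %in% pr[dup]), collapse = ", "))
  if (any(bt < 5 | bt > 50))
    warnf("bath temperatures outside the conventional 5-50 degC calibrated range")

  fit_one <- function(d) {
    if (length(pr) < d + 2) return(NULL)
    fit <- stats::lm(bt ~ stats::poly(pr, degree = d, raw = TRUE))
    s <- summary(fit)
    list(fit = fit, degree = d, r2 = s$r.squared, adj_r2 = s$adj.r.squared)
  }

  if (is.null(degree)) {
    cands <- Filter(Negate(is.null), lapply(2:4, fit_one))
    if (!length(cands)) stopf("need at least %d points for a degree-2 fit", 4L)
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "adj_r2"))]]
  } else {
    if (!is_count(degree)) stopf("`degree` must be a positive integer")
    if (length(pr) < degree + 2)
      stopf("insufficient points: degree %d needs at least %d, got %d",
            degree, degree + 2, length(pr))
    best <- fit_one(degree)
  }
  if (best$r2 <= 0.98)
    warnf("calibration R-squared = %.4f does not exceed 0.98", best$r2)

  structure(list(
    coefficients  = unname(stats::coef(best$fit)),
    degree        = best$degree,
    r_squared     = best$r2,
    adj_r_squared = best$adj_r2,
    valid_range   = range(bt),
    x_range       = range(pr),
    fitted_on     = length(pr),
    x_type        = x
  ), class = "calibration_curve")
}

#' Evaluate a calibration curve
#'
#' Converts raw transmitter readings to temperature by evaluating the fitted
#' polynomial. Readings whose implied temperature falls outside the curve's
#' calibrated temperature range are returned (never dropped) but flagged as
#' extrapolations, since field records contain dropouts and out-of-band
#' pulses.
#'
#' @param curve a `calibration_curve`.
#' @param pulse_rate numeric vector of raw readings.
#' @return data.frame with columns `pulse_rate`, `temperature` (degC) and
#'   logical `extrapolated`.
#' @export
pulse_to_temperature <- function(curve, pulse_rate) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(pulse_rate) || any(!is.finite(pulse_rate)))
    stopf("`pulse_rate` must be finite numeric")
  temp <- eval_poly(curve$coefficients, pulse_rate)
  data.frame(
    pulse_rate = pulse_rate,
    temperature = temp,
    extrapolated = temp < curve$valid_range[1] | temp > curve$valid_range[2]
  )
}

#' @keywords internal
#' @noRd
eval_poly <- function(coefs, x) {
  # Horner evaluation, intercept-first coefficient order
  out <- rep(coefs[length(coefs)], length(x))
  for (k in rev(seq_len(length(coefs) - 1))) out <- out * x + coefs[k]
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (degree %d, fitted on %d points)\n",
              x$degree, x$fitted_on))
  cat(sprintf("  predictor: %s\n", x$x_type))
  cat(sprintf("  R-squared: %.4f (adj. %.4f)\n", x$r_squared, x$adj_r_squared))
  cat(sprintf("  valid range: %.1f to %.1f degC\n",
              x$valid_range[1], x$valid_range[2]))
  cat("  coefficients:", format(x$coefficients, digits = 6), "\n")
  invisible(x)
}

#' Serialize / restore calibration curves
#'
#' Curves round-trip through a small YAML document carrying the coefficients,
#' degree, fit diagnostics and calibrated ranges.
#'
#' @param curve a `calibration_curve`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `calibration_curve`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  yaml::write_yaml(unclass(curve), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$coefficients <- as.numeric(obj$coefficients)
  obj$valid_range <- as.numeric(obj$valid_range)
  obj$x_range <- as.numeric(obj$x_range)
  structure(obj, class = "calibration_curve")
}
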