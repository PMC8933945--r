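#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal on concentration, with the figures of
#' merit used for linearity assessment: r-squared (squared Pearson
#' correlation) and the residual standard deviation
#' `sqrt(SSE / (n - 2))`.
#'
#' @param levels Data.frame with numeric columns `concentration` (ug/mL,
#'   >= 0) and `signal`; at least 3 distinct concentrations.
#' @param wavelength_nm Channel wavelength the curve belongs to.
#' @param deriv_order Derivative order of the channel signal (0, 1 or 2).
#' @return A `"calibration_curve"` with `slope`, `intercept`, `r2`,
#'   `residual_sd`, `range_low`, `range_high`, `n_levels`,
#'   `wavelength_nm`, `deriv_order`.
#' @examples
#' lv <- data.frame(concentration = c(20, 40, 60, 80, 100, 120))
#' lv$signal <- 0.0068 * lv$concentration + 0.005
#' fit_calibration(lv, 253, 1)
#' @export
fit_calibration <- function(levels, wavelength_nm, deriv_order) {
  stopifnot(is.data.frame(levels),
            all(c("concentration", "signal") %in% names(levels)))
  conc <- levels$concentration
  sig <- levels$signal
  if (any(conc < 0)) {
    stop("fit_calibration: concentrations must be >= 0", call. = FALSE)
  }
  if (length(conc) < 3L) {
    stop("fit_calibration: need at least 3 calibration points",
         call. = FALSE)
  }
  if (length(unique(conc)) < 2L) {
    stop("fit_calibration: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(sig ~ conc)
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (stats::sd(sig) == 0) NA_real_ else stats::cor(conc, sig)^2
  structure(
    list(wavelength_nm = wavelength_nm, deriv_order = as.integer(deriv_order),
         slope = unname(co["conc"]), intercept = unname(co["(Intercept)"]),
         r2 = r2, residual_sd = sqrt(sse / (length(conc) - 2)),
         range_low = min(conc), range_high = max(conc),
         n_levels = length(unique(conc))),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %g nm D%d: y = %.4gx %s %.4g, r2 = %.4f\n",
    x$wavelength_nm, x$deriv_order, x$slope,
    if (x$intercept < 0) "-" else "+", abs(x$intercept), x$r2))
  cat(sprintf("  range %g-%g ug/mL (%d levels), residual sd %.3g\n",
              x$range_low, x$range_high, x$n_levels, x$residual_sd))
  invisible(x)
}

#' Predicted signal at a concentration
#'
#' @param curve A `"calibration_curve"`.
#' @param conc Concentration(s) (ug/mL).
#' @return Numeric signal(s).
#' @export
predict_signal <- function(curve, conc) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * conc + curve$intercept
}

#' Inverse prediction: signal to concentration
#'
#' `(signal - intercept) / slope`. A warning is raised (and recorded in
#' the `"outside_range"` attribute) when the estimate falls outside the
#' calibrated range.
#'
#' @param curve A `"calibration_curve"` with non-zero slope.
#' @param signal Observed signal(s).
#' @return Estimated concentration(s) (ug/mL), with attribute
#'   `"outside_range"`.
#' @export
invert_calibration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop("invert_calibration: zero slope", call. = FALSE)
  }
  conc <- (signal - curve$intercept) / curve$slope
  out <- conc < curve$range_low | conc > curve$range_high
  if (any(out)) {
    warning("invert_calibration: estimate outside the calibrated range [",
            curve$range_low, ", ", curve$range_high, "] ug/mL",
            call. = FALSE)
  }
  attr(conc, "outside_range") <- out
  conc
}

#' ICH limits of detection and quantification
#'
#' `LOD = 3.3 * sigma / S` and `LOQ = 10 * sigma / S`, with `sigma` the
#' residual standard deviation of the calibration regression and `S` its
#' slope; consequently `LOQ / LOD = 10 / 3.3` for every curve.
#'
#' @param curve A `"calibration_curve"` with positive slope.
#' @return List with elements `lod` and `loq` (ug/mL).
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) {
    stop("lod_loq: slope must be positive", call. = FALSE)
  }
  list(lod = 3.3 * curve$residual_sd / curve$slope,
       loq = 10 * curve$residual_sd / curve$slope)
}

#' Linearity acceptance report
#'
#' One row per curve with the regression parameters, figures of merit and
#' a pass/fail flag (`r2 >= r2_min` and positive slope).
#'
#' @param curves List of `"calibration_curve"` objects (possibly empty).
#' @param r2_min Minimum acceptable r-squared (default 0.999).
#' @return Data.frame with columns `wavelength_nm`, `deriv_order`,
#'   `slope`, `intercept`, `r2`, `residual_sd`, `lod`, `loq`,
#'   `range_low`, `range_high`, `n_levels`, `pass`.
#' @export
linearity_report <- function(curves, r2_min = 0.999) {
  rows <- lapply(curves, function(cv) {
    lim <- if (cv$slope > 0) lod_loq(cv) else list(lod = NA_real_,
                                                   loq = NA_real_)
    data.frame(wavelength_nm = cv$wavelength_nm,
               deriv_order = cv$deriv_order,
               slope = cv$slope, intercept = cv$intercept, r2 = cv$r2,
               residual_sd = cv$residual_sd, lod = lim$lod, loq = lim$loq,
               range_low = cv$range_low, range_high = cv$range_high,
               n_levels = cv$n_levels,
               pass = isTRUE(cv$r2 >= r2_min) && cv$slope > 0)
  })
  if (!length(rows)) {
    return(data.frame(wavelength_nm = numeric(0), deriv_order = integer(0),
                      slope = numeric(0), intercept = numeric(0),
                      r2 = numeric(0), residual_sd = numeric(0),
                      lod = numeric(0), loq = numeric(0),
                      range_low = numeric(0), range_high = numeric(0),
                      n_levels = integer(0), pass = logical(0)))
  }
  do.call(rbind, rows)
}
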