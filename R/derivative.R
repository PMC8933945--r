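#' Savitzky-Golay smoother settings
#'
#' @param window_points Odd filter length; must be at least
#'   `poly_order + 2`. Default 15 points (1.5 nm on the default grid).
#' @param poly_order Local polynomial degree; must be at least the
#'   derivative order requested later. Default 3.
#' @return A `"smoother_params"` object.
#' @export
smoother_params <- function(window_points = 15L, poly_order = 3L) {
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (window_points %% 2L == 0L) {
    stop("smoother_params: window_points must be odd", call. = FALSE)
  }
  if (window_points < poly_order + 2L) {
    stop("smoother_params: window_points must be >= poly_order + 2",
         call. = FALSE)
  }
  structure(list(window_points = window_points, poly_order = poly_order),
            class = "smoother_params")
}

new_deriv <- function(grid, values, order, amplification, meta = list()) {
  structure(list(grid = grid, values = values, order = as.integer(order),
                 amplification = amplification, meta = meta),
            class = "uv_deriv")
}

#' @export
print.uv_deriv <- function(x, ...) {
  cat(sprintf("<uv_deriv> order %d (x%g), %g-%g nm (%d pts)\n",
              x$order, x$amplification, x$grid$start_nm, x$grid$stop_nm,
              grid_length(x$grid)))
  invisible(x)
}

#' Amplified Savitzky-Golay derivative spectrum
#'
#' Differentiates the absorbance trace with respect to wavelength using a
#' Savitzky-Golay filter and multiplies by the amplification factor. The
#' operator is linear, which is the mathematical basis of zero-crossing
#' quantification: the derivative of a mixture is the sum of its
#' components' derivatives.
#'
#' @param s A `"uv_spectrum"`.
#' @param order Derivative order, 1 or 2.
#' @param params A [smoother_params()]; `poly_order` must be >= `order`.
#' @param amplification Uniform scale factor (default 10, the conventional
#'   "x10" display amplification, absorbed into calibration slopes).
#' @return A `"uv_deriv"` in AU/nm^order times amplification.
#' @export
derivative_spectrum <- function(s, order, params = smoother_params(),
                                amplification = 10) {
  stopifnot(inherits(s, "uv_spectrum"), inherits(params, "smoother_params"))
  if (!(order %in% c(1L, 2L))) {
    stop("derivative_spectrum: order must be 1 or 2", call. = FALSE)
  }
  if (params$poly_order < order) {
    stop("derivative_spectrum: poly_order must be >= derivative order",
         call. = FALSE)
  }
  n <- grid_length(s$grid)
  if (params$window_points > n) {
    stop("derivative_spectrum: smoothing window larger than spectrum",
         call. = FALSE)
  }
  vals <- signal::sgolayfilt(s$absorbance, p = params$poly_order,
                             n = params$window_points, m = order,
                             ts = s$grid$step_nm)
  new_deriv(s$grid, amplification * vals, order, amplification,
            meta = c(s$meta, list(smoother = unclass(params))))
}

#' Central finite-difference derivative (reference oracle)
#'
#' Unsmoothed central differences, intended as an independent reference for
#' testing the Savitzky-Golay path, not for production use. Endpoint values
#' use one-sided differences.
#'
#' @param s A `"uv_spectrum"`.
#' @param order Derivative order, 1 or 2.
#' @param amplification Scale factor; default 1 (raw derivative units).
#' @return A `"uv_deriv"`.
#' @export
finite_difference_oracle <- function(s, order, amplification = 1) {
  stopifnot(inherits(s, "uv_spectrum"))
  if (!(order %in% c(1L, 2L))) {
    stop("finite_difference_oracle: order must be 1 or 2", call. = FALSE)
  }
  n <- grid_length(s$grid)
  if (n < 2L * order + 1L) {
    stop("finite_difference_oracle: need at least 2*order + 1 points",
         call. = FALSE)
  }
  y <- s$absorbance
  h <- s$grid$step_nm
  v <- numeric(n)
  i <- 2:(n - 1)
  if (order == 1L) {
    v[i] <- (y[i + 1] - y[i - 1]) / (2 * h)
    v[1] <- (y[2] - y[1]) / h
    v[n] <- (y[n] - y[n - 1]) / h
  } else {
    v[i] <- (y[i + 1] - 2 * y[i] + y[i - 1]) / h^2
    v[1] <- v[2]
    v[n] <- v[n - 1]
  }
  new_deriv(s$grid, amplification * v, order, amplification, meta = s$meta)
}

#' Read a signal at an arbitrary wavelength
#'
#' Linear interpolation between the bracketing grid points; exact at grid
#' points. Works on both zero-order spectra and derivative spectra.
#'
#' @param x A `"uv_spectrum"` or `"uv_deriv"`.
#' @param wavelength_nm Query wavelength(s), inside the grid range.
#' @return Numeric signal value(s).
#' @export
signal_at <- function(x, wavelength_nm) {
  grid <- x$grid
  vals <- if (inherits(x, "uv_deriv")) x$values else x$absorbance
  wl <- grid$wavelength
  if (any(wavelength_nm < wl[1] - 1e-9 |
          wavelength_nm > wl[length(wl)] + 1e-9)) {
    stop("signal_at: wavelength outside the grid range", call. = FALSE)
  }
  pos <- (wavelength_nm - grid$start_nm) / grid$step_nm
  i <- pmin(pmax(floor(pos), 0), length(wl) - 2)
  frac <- pos - i
  # land exactly on stored values at grid points
  frac[abs(frac) < 1e-9] <- 0
  frac[abs(frac - 1) < 1e-9] <- 1
  vals[i + 1] * (1 - frac) + vals[i + 2] * frac
}

#' Zero-crossing wavelengths common to a spectral family
#'
#' Finds wavelengths where the amplified derivative of *every* family
#' member (an interferent at several concentrations, plus any formulation
#' spectra) is zero within tolerance, and where at least one member
#' genuinely changes sign within 1 nm (a true crossing, not a flat tail).
#' At such a wavelength the derivative signal of a mixture belongs
#' entirely to the other component.
#'
#' Derivative values within half a smoothing window of the grid edges are
#' excluded from the search.
#'
#' @param family Non-empty list of `"uv_spectrum"` objects on one grid.
#' @param order Derivative order, 1 or 2.
#' @param params A [smoother_params()].
#' @param amplification Derivative amplification (default 10).
#' @param tolerance Absolute tolerance on the amplified derivative
#'   magnitude at a crossing. `NULL` defaults to 1% of the largest
#'   derivative magnitude observed in the family.
#' @return A data.frame with columns `order`, `wavelength_nm`,
#'   `max_abs_family_value`, sorted by wavelength. Zero rows when no common
#'   crossing exists.
#' @export
find_common_zero_crossings <- function(family, order,
                                       params = smoother_params(),
                                       amplification = 10,
                                       tolerance = NULL) {
  if (!is.list(family) || length(family) == 0L) {
    stop("find_common_zero_crossings: family must be a non-empty list",
         call. = FALSE)
  }
  grid <- family[[1]]$grid
  for (s in family) {
    if (!same_grid(grid, s$grid)) {
      stop("find_common_zero_crossings: family members on mixed grids",
           call. = FALSE)
    }
  }
  derivs <- lapply(family, derivative_spectrum, order = order,
                   params = params, amplification = amplification)
  half <- (params$window_points - 1L) %/% 2L
  n <- grid_length(grid)
  keep <- (half + 1L):(n - half)
  wl <- grid$wavelength
  if (is.null(tolerance)) {
    tolerance <- 0.01 * max(vapply(derivs, function(d)
      max(abs(d$values[keep])), 0))
  }

  # candidate roots: strict sign changes in any member, linearly interpolated
  # (a relative dust filter keeps floating-point noise in flat tails out)
  roots <- numeric(0)
  for (d in derivs) {
    v <- d$values
    dust <- 1e-9 * max(abs(v[keep]))
    i <- keep[-length(keep)]
    sc <- which(v[i] * v[i + 1] < 0 & pmax(abs(v[i]), abs(v[i + 1])) > dust)
    if (length(sc)) {
      ii <- i[sc]
      roots <- c(roots, wl[ii] + grid$step_nm * v[ii] / (v[ii] - v[ii + 1]))
    }
  }
  if (!length(roots)) {
    return(data.frame(order = integer(0), wavelength_nm = numeric(0),
                      max_abs_family_value = numeric(0)))
  }

  # cluster roots within 0.5 nm, candidate = cluster mean
  roots <- sort(roots)
  cluster <- cumsum(c(1, diff(roots) > 0.5))
  cands <- as.numeric(tapply(roots, cluster, mean))

  win <- max(1L, round(5 / grid$step_nm))
  out <- lapply(cands, function(lam) {
    at <- vapply(derivs, signal_at, 0, wavelength_nm = lam)
    if (any(abs(at) > tolerance)) return(NULL)
    # non-flatness: some member must rise above tolerance nearby
    j <- round((lam - grid$start_nm) / grid$step_nm) + 1L
    lo <- max(1L, j - win); hi <- min(n, j + win)
    lively <- any(vapply(derivs, function(d)
      max(abs(d$values[lo:hi])) > tolerance, TRUE))
    if (!lively) return(NULL)
    data.frame(order = as.integer(order), wavelength_nm = lam,
               max_abs_family_value = max(abs(at)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(order = integer(0), wavelength_nm = numeric(0),
                      max_abs_family_value = numeric(0))
  }
  out[order(out$wavelength_nm), , drop = FALSE]
}

#' Pick the working wavelength among candidate crossings
#'
#' Selects the crossing where the analyte's own derivative magnitude is
#' largest (maximum sensitivity); exact ties break to the lowest
#' wavelength.
#'
#' @param crossings Data.frame from [find_common_zero_crossings()],
#'   non-empty.
#' @param analyte_deriv The analyte's `"uv_deriv"` at the same order.
#' @return One-row data.frame: the chosen crossing plus `analyte_value`.
#' @export
select_working_wavelength <- function(crossings, analyte_deriv) {
  if (!is.data.frame(crossings) || nrow(crossings) == 0L) {
    stop("select_working_wavelength: empty crossing list", call. = FALSE)
  }
  val <- signal_at(analyte_deriv, crossings$wavelength_nm)
  crossings$analyte_value <- val
  best <- which(abs(val) == max(abs(val)))
  if (length(best) > 1L) best <- best[which.min(crossings$wavelength_nm[best])]
  crossings[best, , drop = FALSE]
}
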