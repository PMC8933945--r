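#' Assay channel
#'
#' One (wavelength, derivative order, calibration curve) triple used by the
#' binary assay. Channels can be flagged not applicable — e.g. the 245 nm
#' D2 channel under the cream matrix, whose excipients destroy that
#' zero-crossing.
#'
#' @param wavelength_nm Working wavelength (nm).
#' @param order Derivative order (0, 1 or 2).
#' @param curve A `"calibration_curve"` fitted at this channel.
#' @param label Channel label, default `"<wavelength>/D<order>"` using the
#'   nominal wavelength.
#' @param nominal_nm Nominal (literature) wavelength for labelling;
#'   defaults to the working wavelength rounded to 1 nm.
#' @param applicable Logical; `FALSE` marks a channel that must be
#'   reported as not applicable rather than as a number.
#' @return An `"assay_channel"` object.
#' @export
assay_channel <- function(wavelength_nm, order, curve, label = NULL,
                          nominal_nm = round(wavelength_nm),
                          applicable = TRUE) {
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_curve"))
    if (curve$deriv_order != order) {
      stop("assay_channel: curve order does not match channel order",
           call. = FALSE)
    }
  }
  if (is.null(label)) label <- sprintf("%g/D%d", nominal_nm, order)
  structure(list(wavelength_nm = wavelength_nm, order = as.integer(order),
                 curve = curve, label = label, nominal_nm = nominal_nm,
                 applicable = isTRUE(applicable)),
            class = "assay_channel")
}

#' Binary assay configuration
#'
#' Bundles the NCT derivative channels (nominally 253/D1, 245/D2, 269/D2),
#' the TRT zero-order channel at 348 nm, and the smoother/amplification
#' settings that calibration and assay must share.
#'
#' @param nct_channels List of [assay_channel()]s for the analyte read at
#'   interferent zero-crossings.
#' @param trt_channel [assay_channel()] for the zero-order analyte.
#' @param params A [smoother_params()].
#' @param amplification Derivative amplification factor.
#' @return A `"binary_assay_config"` object.
#' @export
binary_assay_config <- function(nct_channels, trt_channel,
                                params = smoother_params(),
                                amplification = 10) {
  stopifnot(is.list(nct_channels),
            all(vapply(nct_channels, inherits, TRUE, "assay_channel")),
            inherits(trt_channel, "assay_channel"))
  structure(list(nct_channels = nct_channels, trt_channel = trt_channel,
                 params = params, amplification = amplification),
            class = "binary_assay_config")
}

#' Build a calibrated assay configuration from a component library
#'
#' Resolves the working wavelengths from detected zero-crossings of the
#' TRT family (including the formulation spectrum when a matrix is
#' stated), simulates noiseless standard series, and fits one calibration
#' curve per channel at the resolved wavelength. Under the cream matrix
#' the 245 nm D2 channel is flagged not applicable.
#'
#' @param library A `"component_library"` from
#'   [builtin_component_library()].
#' @param formulation `"pure"`, `"solution"` or `"cream"`; which excipient
#'   background the assay must tolerate.
#' @param nct_levels,trt_levels Standard-series concentrations (ug/mL).
#' @return A `"binary_assay_config"`.
#' @export
build_assay_config <- function(library,
                               formulation = c("pure", "solution", "cream"),
                               nct_levels = c(20, 40, 60, 80, 100, 120),
                               trt_levels = seq(0.5, 5, by = 0.5)) {
  stopifnot(inherits(library, "component_library"))
  formulation <- match.arg(formulation)
  comps <- library$components
  grid <- library$grid
  params <- library$params
  amp <- library$amplification

  d1 <- trt_family_crossings(comps, grid, params, amp, 1L, formulation)
  d2 <- trt_family_crossings(comps, grid, params, amp, 2L, formulation)
  lam <- c(`253` = nearest_crossing(d1, 253, 2),
           `245` = nearest_crossing(d2, 245, 2),
           `269` = nearest_crossing(d2, 269, 2))
  if (is.na(lam["253"]) || is.na(lam["269"])) {
    stop("build_assay_config: required zero-crossing missing (253/D1 or ",
         "269/D2)", call. = FALSE)
  }

  nct_specs <- list(list(nom = 253, order = 1L, lam = lam[["253"]]),
                    list(nom = 245, order = 2L, lam = lam[["245"]]),
                    list(nom = 269, order = 2L, lam = lam[["269"]]))
  nct_channels <- lapply(nct_specs, function(sp) {
    if (is.na(sp$lam)) {
      return(assay_channel(NA_real_, sp$order, curve = NULL,
                           nominal_nm = sp$nom, applicable = FALSE))
    }
    sig <- vapply(nct_levels, function(cc) {
      s <- component_spectrum(comps$NCT, cc, grid)
      signal_at(derivative_spectrum(s, sp$order, params, amp), sp$lam)
    }, 0)
    cv <- fit_calibration(data.frame(concentration = nct_levels,
                                     signal = sig), sp$lam, sp$order)
    assay_channel(sp$lam, sp$order, cv, nominal_nm = sp$nom)
  })

  sig348 <- vapply(trt_levels, function(cc)
    signal_at(component_spectrum(comps$TRT, cc, grid), 348), 0)
  trt_curve <- fit_calibration(data.frame(concentration = trt_levels,
                                          signal = sig348), 348, 0L)
  trt_channel <- assay_channel(348, 0L, trt_curve)

  binary_assay_config(nct_channels, trt_channel, params, amp)
}

#' Assay a binary-mixture spectrum
#'
#' Derives the spectrum to each NCT channel's order, reads the amplified
#' derivative at the channel's zero-crossing wavelength and inverts the
#' channel calibration; TRT is read in zero order at 348 nm. When nominal
#' concentrations are supplied, recoveries (100 x estimated / nominal) are
#' reported.
#'
#' @param spectrum A `"uv_spectrum"` on the calibration grid.
#' @param config A `"binary_assay_config"`.
#' @param nominal Optional named vector, e.g. `c(NCT = 80, TRT = 2)`.
#' @return Data.frame with one row per channel: `channel`, `analyte`,
#'   `wavelength_nm`, `deriv_order`, `signal`, `estimate`, `nominal`,
#'   `recovery`. Not-applicable channels report `NA` estimates.
#' @export
assay_binary_mixture <- function(spectrum, config, nominal = NULL) {
  stopifnot(inherits(spectrum, "uv_spectrum"),
            inherits(config, "binary_assay_config"))
  orders <- unique(vapply(Filter(function(ch) ch$applicable,
                                 config$nct_channels), `[[`, 0L, "order"))
  derivs <- lapply(orders, function(o)
    derivative_spectrum(spectrum, o, config$params, config$amplification))
  names(derivs) <- as.character(orders)

  nom_of <- function(analyte) {
    if (!is.null(nominal) && analyte %in% names(nominal))
      nominal[[analyte]] else NA_real_
  }
  row_of <- function(ch, analyte) {
    nom <- nom_of(analyte)
    if (!ch$applicable) {
      return(data.frame(channel = ch$label, analyte = analyte,
                        wavelength_nm = NA_real_,
                        deriv_order = ch$order, signal = NA_real_,
                        estimate = NA_real_, nominal = nom,
                        recovery = NA_real_))
    }
    if (is.null(ch$curve)) {
      stop("assay_binary_mixture: channel ", ch$label,
           " has no calibration curve", call. = FALSE)
    }
    sig <- if (ch$order == 0L) signal_at(spectrum, ch$wavelength_nm)
    else signal_at(derivs[[as.character(ch$order)]], ch$wavelength_nm)
    est <- suppressWarnings(as.numeric(invert_calibration(ch$curve, sig)))
    data.frame(channel = ch$label, analyte = analyte,
               wavelength_nm = ch$wavelength_nm, deriv_order = ch$order,
               signal = sig, estimate = est, nominal = nom,
               recovery = if (is.na(nom) || nom <= 0) NA_real_
               else recovery_percent(est, nom))
  }
  out <- do.call(rbind, c(lapply(config$nct_channels, row_of, "NCT"),
                          list(row_of(config$trt_channel, "TRT"))))
  rownames(out) <- NULL
  out
}

#' Standard-addition series
#'
#' @param added_concs Added analyte concentrations on the final-flask
#'   basis (ug/mL); must include 0 and be strictly increasing.
#' @param signals Measured signals, one per addition level.
#' @param wavelength_nm,order Channel the signals were read at (metadata).
#' @return A `"standard_addition_series"` object.
#' @export
standard_addition_series <- function(added_concs, signals,
                                     wavelength_nm = NA_real_,
                                     order = NA_integer_) {
  if (length(added_concs) != length(signals)) {
    stop("standard_addition_series: added_concs and signals lengths differ",
         call. = FALSE)
  }
  if (!any(added_concs == 0)) {
    stop("standard_addition_series: additions must include 0", call. = FALSE)
  }
  if (any(diff(added_concs) <= 0)) {
    stop("standard_addition_series: additions must be strictly increasing",
         call. = FALSE)
  }
  structure(list(added_concs = added_concs, signals = signals,
                 wavelength_nm = wavelength_nm, order = order),
            class = "standard_addition_series")
}

#' Standard-additions estimate of the base concentration
#'
#' Fits signal against added concentration by OLS and extrapolates to the
#' x-intercept: the base concentration is `intercept / slope` (the
#' magnitude of the extrapolated intercept), on the final-flask basis.
#' Dilution back to the original sample is the caller's arithmetic (see
#' [prep_concentration_calculator()]).
#'
#' @param series A [standard_addition_series()] with at least 3 levels.
#' @return Base concentration (ug/mL).
#' @export
standard_additions_estimate <- function(series) {
  stopifnot(inherits(series, "standard_addition_series"))
  if (length(series$added_concs) < 3L) {
    stop("standard_additions_estimate: need at least 3 addition levels",
         call. = FALSE)
  }
  x <- series$added_concs
  y <- series$signals
  co <- stats::coef(stats::lm(y ~ x))
  if (co[["x"]] <= 0) {
    stop("standard_additions_estimate: non-positive slope - invalid series",
         call. = FALSE)
  }
  co[["(Intercept)"]] / co[["x"]]
}

#' Recovery percentage
#'
#' @param estimated Estimated concentration (ug/mL).
#' @param nominal True/nominal concentration (ug/mL), > 0.
#' @return `100 * estimated / nominal`.
#' @export
recovery_percent <- function(estimated, nominal) {
  if (any(nominal <= 0)) {
    stop("recovery_percent: nominal must be > 0", call. = FALSE)
  }
  100 * estimated / nominal
}
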