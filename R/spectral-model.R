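#' Gaussian absorption band
#'
#' One Gaussian component of a molar-absorptivity curve:
#' `eps(lambda) = amplitude * exp(-(lambda - center)^2 / (2 sigma^2))`,
#' in AU per (ug/mL) at unit path length.
#'
#' @param center_nm Band centre (nm).
#' @param sigma_nm Band width (nm), positive.
#' @param amplitude Peak absorptivity (AU mL/ug). Analyte bands must be
#'   non-negative; negative amplitudes are only admitted inside background
#'   (excipient) models.
#' @return A `"gaussian_band"` object.
#' @export
gaussian_band <- function(center_nm, sigma_nm, amplitude) {
  stopifnot(is.numeric(center_nm), is.numeric(sigma_nm), is.numeric(amplitude))
  if (sigma_nm <= 0) stop("gaussian_band: sigma_nm must be > 0", call. = FALSE)
  structure(list(center_nm = center_nm, sigma_nm = sigma_nm,
                 amplitude = amplitude),
            class = "gaussian_band")
}

#' Component absorptivity model
#'
#' A named set of Gaussian bands whose sum is the component's absorptivity
#' curve. Backgrounds (formulation excipients) are flagged with
#' `background = TRUE`: they are carried at unit "concentration" in a
#' mixture and may contain negative-amplitude bands.
#'
#' @param name Component label, e.g. `"NCT"`.
#' @param bands List of [gaussian_band()] objects.
#' @param background Logical; excipient background rather than analyte.
#' @return A `"component_model"` object.
#' @export
component_model <- function(name, bands, background = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.list(bands))
  bands <- lapply(bands, function(b) {
    if (!inherits(b, "gaussian_band")) {
      b <- gaussian_band(b$center_nm, b$sigma_nm, b$amplitude)
    }
    b
  })
  if (!background && any(vapply(bands, `[[`, 0, "amplitude") < 0)) {
    stop("component_model: negative band amplitudes are only allowed in ",
         "background models", call. = FALSE)
  }
  structure(list(name = name, bands = bands, background = isTRUE(background)),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model> %s%s, %d band(s)\n", x$name,
              if (x$background) " [background]" else "", length(x$bands)))
  for (b in x$bands) {
    cat(sprintf("  center %7.3f nm  sigma %6.3f nm  amplitude %.6g\n",
                b$center_nm, b$sigma_nm, b$amplitude))
  }
  invisible(x)
}

#' Absorptivity of a component model
#'
#' Evaluates the summed Gaussian bands at the given wavelengths.
#'
#' @param model A [component_model()].
#' @param wavelength_nm Numeric vector of wavelengths (nm).
#' @return Numeric vector of absorptivities (AU mL/ug).
#' @export
absorptivity <- function(model, wavelength_nm) {
  stopifnot(inherits(model, "component_model"))
  out <- numeric(length(wavelength_nm))
  for (b in model$bands) {
    out <- out +
      b$amplitude * exp(-(wavelength_nm - b$center_nm)^2 / (2 * b$sigma_nm^2))
  }
  out
}

#' Construct a spectrum from raw values
#'
#' Low-level constructor for wrapping externally acquired (or hand-built)
#' absorbance traces; most spectra come from [component_spectrum()],
#' [mix_spectrum()] or [read_spectrum_csv()].
#'
#' @param grid A [wavelength_grid()].
#' @param absorbance Finite numeric vector, one value per grid point.
#' @param meta Free-form provenance list.
#' @return A `"uv_spectrum"`.
#' @export
new_spectrum <- function(grid, absorbance, meta = list()) {
  stopifnot(inherits(grid, "wavelength_grid"),
            length(absorbance) == grid_length(grid))
  if (any(!is.finite(absorbance))) {
    stop("spectrum: absorbance values must be finite", call. = FALSE)
  }
  structure(list(grid = grid, absorbance = absorbance, meta = meta),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %g-%g nm (%d pts), max %.4g AU at %.1f nm\n",
              x$grid$start_nm, x$grid$stop_nm, grid_length(x$grid),
              max(x$absorbance),
              x$grid$wavelength[which.max(x$absorbance)]))
  invisible(x)
}

#' Beer-Lambert spectrum of a single component
#'
#' `A(lambda) = conc * eps(lambda)`: degree-1 homogeneous in concentration.
#'
#' @param model A [component_model()].
#' @param conc Concentration (ug/mL), non-negative. Backgrounds are
#'   conventionally simulated at `conc = 1`.
#' @param grid A [wavelength_grid()].
#' @return A `"uv_spectrum"`.
#' @export
component_spectrum <- function(model, conc, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.numeric(conc) || length(conc) != 1L || conc < 0) {
    stop("component_spectrum: conc must be a single non-negative number",
         call. = FALSE)
  }
  new_spectrum(grid, conc * absorptivity(model, grid$wavelength),
               meta = list(component = model$name, conc = conc))
}

#' Additive mixture spectrum
#'
#' Sums the Beer-Lambert responses of the named components; additivity is
#' exact by construction. Background components listed in `sample` are
#' weighted like any other (use weight 1 for "the excipients are present").
#'
#' @param sample Named numeric vector of concentrations (ug/mL); names must
#'   exist in `library`. An empty vector yields the all-zero spectrum.
#' @param library Named list of [component_model()]s.
#' @param grid A [wavelength_grid()].
#' @return A `"uv_spectrum"`.
#' @examples
#' lib <- builtin_component_library(wavelength_grid(200, 400, 0.5))
#' s <- mix_spectrum(c(NCT = 40, TRT = 1), lib$components, lib$grid)
#' @export
mix_spectrum <- function(sample, library, grid) {
  stopifnot(inherits(grid, "wavelength_grid"), is.list(library))
  if (length(sample) && is.null(names(sample))) {
    stop("mix_spectrum: sample must be a named concentration vector",
         call. = FALSE)
  }
  if (any(sample < 0)) {
    stop("mix_spectrum: concentrations must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(names(sample), names(library))
  if (length(unknown)) {
    stop("mix_spectrum: unknown component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absorb <- numeric(grid_length(grid))
  for (nm in names(sample)) {
    absorb <- absorb +
      component_spectrum(library[[nm]], sample[[nm]], grid)$absorbance
  }
  new_spectrum(grid, absorb, meta = list(sample = as.list(sample)))
}

#' Homoscedastic photometric noise model
#'
#' @param sigma_AU Absorbance noise standard deviation (AU), >= 0. The
#'   default 0.002 AU is typical photometric noise for zero-order work.
#' @param seed Optional integer seed; the same seed and input always
#'   reproduce the same noisy spectrum. `NULL` uses (and advances) the
#'   session RNG.
#' @return A `"noise_model"` object.
#' @export
noise_model <- function(sigma_AU = 0.002, seed = NULL) {
  stopifnot(is.numeric(sigma_AU), length(sigma_AU) == 1L)
  if (sigma_AU < 0) stop("noise_model: sigma_AU must be >= 0", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sigma_AU = sigma_AU, seed = seed), class = "noise_model")
}

#' Add i.i.d. Gaussian noise to a spectrum
#'
#' With `sigma_AU = 0` the spectrum is returned unchanged. When the noise
#' model carries a seed, the caller's RNG state is saved and restored so
#' seeded simulation never perturbs the session stream.
#'
#' @param s A `"uv_spectrum"`.
#' @param noise A [noise_model()].
#' @return A `"uv_spectrum"`.
#' @export
add_noise <- function(s, noise) {
  stopifnot(inherits(s, "uv_spectrum"), inherits(noise, "noise_model"))
  if (noise$sigma_AU == 0) return(s)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(noise$seed)
  }
  draws <- stats::rnorm(grid_length(s$grid), mean = 0, sd = noise$sigma_AU)
  new_spectrum(s$grid, s$absorbance + draws,
               meta = c(s$meta, list(noise_sigma_AU = noise$sigma_AU)))
}

#' Apply an instrumental bandwidth (slit) kernel
#'
#' Convolves the absorbance trace with a normalised Gaussian kernel of the
#' given standard deviation, emulating the spectral bandwidth of the
#' monochromator. The kernel is renormalised at the grid edges.
#'
#' @param s A `"uv_spectrum"`.
#' @param sd_nm Kernel standard deviation (nm); 0 returns `s` unchanged.
#' @return A `"uv_spectrum"`.
#' @export
apply_bandwidth <- function(s, sd_nm) {
  stopifnot(inherits(s, "uv_spectrum"), is.numeric(sd_nm), sd_nm >= 0)
  if (sd_nm == 0) return(s)
  h <- s$grid$step_nm
  half <- max(1L, ceiling(5 * sd_nm / h))
  x <- (-half:half) * h
  kern <- exp(-x^2 / (2 * sd_nm^2))
  kern <- kern / sum(kern)
  n <- grid_length(s$grid)
  padded <- c(rep(s$absorbance[1], half), s$absorbance,
              rep(s$absorbance[n], half))
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  out <- as.numeric(sm[(half + 1):(half + n)])
  new_spectrum(s$grid, out, meta = c(s$meta, list(bandwidth_sd_nm = sd_nm)))
}
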