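#' Write / read a spectrum as two-column CSV
#'
#' The format is `wavelength_nm,absorbance` preceded by `# key=value`
#' comment lines carrying provenance metadata. Derivative spectra store
#' `order` and `amplification` in the header and are restored as
#' `"uv_deriv"` objects. Values are written with 9 significant figures, so
#' a round trip is lossless well past the 6 figures the format promises.
#'
#' @param s A `"uv_spectrum"` or `"uv_deriv"`.
#' @param path File path.
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` the restored object.
#' @export
write_spectrum_csv <- function(s, path) {
  is_deriv <- inherits(s, "uv_deriv")
  stopifnot(is_deriv || inherits(s, "uv_spectrum"))
  meta <- s$meta
  hdr <- character(0)
  if (is_deriv) {
    hdr <- c(sprintf("# order=%d", s$order),
             sprintf("# amplification=%.9g", s$amplification))
  }
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.atomic(v) && length(v) == 1L && !is.logical(v)) {
      hdr <- c(hdr, sprintf("# %s=%s", k, format(v, digits = 9)))
    }
  }
  vals <- if (is_deriv) s$values else s$absorbance
  lines <- c(hdr, "wavelength_nm,absorbance",
             sprintf("%.9g,%.9g", s$grid$wavelength, vals))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (m in sub("^#\\s*", "", lines[is_meta])) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      v <- suppressWarnings(as.numeric(kv[2]))
      meta[[trimws(kv[1])]] <- if (is.na(v)) trimws(kv[2]) else v
    }
  }
  body_idx <- which(!is_meta)
  body <- lines[body_idx]
  if (length(body) && grepl("wavelength", body[1], ignore.case = TRUE)) {
    body_idx <- body_idx[-1]
    body <- body[-1]
  }
  if (length(body) < 2L) {
    stop("read_spectrum_csv: fewer than 2 data rows", call. = FALSE)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_cols <- which(lengths(parts) != 2L)
  if (length(bad_cols)) {
    stop("read_spectrum_csv: malformed row at line ", body_idx[bad_cols[1]],
         call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  ab <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(wl) | is.na(ab))
  if (length(bad)) {
    stop("read_spectrum_csv: non-numeric cell at line ", body_idx[bad[1]],
         call. = FALSE)
  }
  d <- diff(wl)
  if (any(d <= 0)) {
    stop("read_spectrum_csv: wavelengths not strictly ascending at line ",
         body_idx[which(d <= 0)[1] + 1L], call. = FALSE)
  }
  step <- d[1]
  if (any(abs(d - step) > 1e-6 * step)) {
    stop("read_spectrum_csv: non-uniform wavelength grid at line ",
         body_idx[which(abs(d - step) > 1e-6 * step)[1] + 1L],
         call. = FALSE)
  }
  grid <- wavelength_grid(wl[1], wl[length(wl)],
                          (wl[length(wl)] - wl[1]) / (length(wl) - 1))
  ord <- meta[["order"]]
  amp <- meta[["amplification"]]
  meta[["order"]] <- NULL
  meta[["amplification"]] <- NULL
  if (!is.null(ord)) {
    new_deriv(grid, ab, as.integer(ord),
              if (is.null(amp)) 1 else amp, meta = meta)
  } else {
    new_spectrum(grid, ab, meta = meta)
  }
}

#' Preparation step (dilution / weighing)
#'
#' One link in a dilution chain: either a weighed mass dissolved to a
#' final volume, or an aliquot of the previous solution diluted to a final
#' volume.
#'
#' @param final_mL Final flask volume (mL), > 0.
#' @param aliquot_mL Aliquot taken from the previous solution (mL).
#' @param mass_mg Weighed solute mass (mg); only valid as the first step.
#' @return A `"prep_step"` object.
#' @export
prep_step <- function(final_mL, aliquot_mL = NULL, mass_mg = NULL) {
  if (final_mL <= 0) stop("prep_step: final volume must be > 0",
                          call. = FALSE)
  if (is.null(aliquot_mL) == is.null(mass_mg)) {
    stop("prep_step: give exactly one of aliquot_mL or mass_mg",
         call. = FALSE)
  }
  if (!is.null(aliquot_mL) && aliquot_mL <= 0) {
    stop("prep_step: aliquot must be > 0", call. = FALSE)
  }
  structure(list(final_mL = final_mL, aliquot_mL = aliquot_mL,
                 mass_mg = mass_mg), class = "prep_step")
}

#' Final concentration of a dilution chain
#'
#' Composes the steps: a mass start gives `mass_mg * 1000 / final_mL`
#' ug/mL; each subsequent aliquot step multiplies by
#' `aliquot_mL / final_mL`.
#'
#' @param steps List of [prep_step()]s; the first may be a mass step, all
#'   others must be aliquot steps.
#' @return Final concentration (ug/mL).
#' @examples
#' # 20 mg into 20 mL -> 1000 ug/mL; 0.5 mL into 20 mL -> 25 ug/mL
#' prep_concentration_calculator(list(prep_step(20, mass_mg = 20),
#'                                    prep_step(20, aliquot_mL = 0.5)))
#' @export
prep_concentration_calculator <- function(steps) {
  stopifnot(is.list(steps), length(steps) >= 1L)
  conc <- NA_real_
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    stopifnot(inherits(st, "prep_step"))
    if (!is.null(st$mass_mg)) {
      if (i != 1L) {
        stop("prep_concentration_calculator: mass step only allowed first",
             call. = FALSE)
      }
      conc <- st$mass_mg * 1000 / st$final_mL
    } else {
      if (i == 1L) {
        stop("prep_concentration_calculator: the chain must start from a ",
             "mass step or a known stock (prepend a mass step)",
         call. = FALSE)
      }
      conc <- conc * st$aliquot_mL / st$final_mL
    }
  }
  conc
}

#' Percent (w/v) to ug/mL
#'
#' `0.1% (w/v) = 1000 ug/mL`.
#'
#' @param percent Concentration in % w/v.
#' @return Concentration in ug/mL.
#' @export
percent_wv_to_ugml <- function(percent) percent * 1e4

#' Scenario configuration
#'
#' A self-contained description of one simulated bench scenario: grid,
#' component library, formulation matrix, nominal mixture, noise, smoother
#' and seed. Serialisable to YAML so any pipeline run is reconstructable
#' from (config file, seed) alone.
#'
#' @param formulation `"pure"`, `"solution"` or `"cream"`.
#' @param grid_start,grid_stop,grid_step Wavelength grid (nm).
#' @param library `"builtin"` or a path to a component-library YAML.
#' @param mixture Named list of nominal concentrations (ug/mL).
#' @param sigma_AU Noise SD.
#' @param seed Integer seed.
#' @param window_points,poly_order Smoother settings.
#' @param amplification Derivative amplification.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(formulation = "pure",
                            grid_start = 200, grid_stop = 400,
                            grid_step = 0.1,
                            library = "builtin",
                            mixture = list(NCT = 80, TRT = 2),
                            sigma_AU = 0, seed = 1L,
                            window_points = 15L, poly_order = 3L,
                            amplification = 10) {
  structure(list(formulation = formulation,
                 grid = list(start_nm = grid_start, stop_nm = grid_stop,
                             step_nm = grid_step),
                 library = library, mixture = mixture,
                 noise = list(sigma_AU = sigma_AU, seed = as.integer(seed)),
                 smoother = list(window_points = as.integer(window_points),
                                 poly_order = as.integer(poly_order)),
                 amplification = amplification),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param path YAML file path.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path, precision = 15L)
  invisible(path)
}

#' @rdname scenario_config
#' @param scenario A `"scenario_config"` (for writing).
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- scenario_config(
    formulation = raw$formulation %||% "pure",
    grid_start = raw$grid$start_nm, grid_stop = raw$grid$stop_nm,
    grid_step = raw$grid$step_nm,
    library = raw$library %||% "builtin",
    mixture = raw$mixture,
    sigma_AU = raw$noise$sigma_AU %||% 0,
    seed = raw$noise$seed %||% 1L,
    window_points = raw$smoother$window_points %||% 15L,
    poly_order = raw$smoother$poly_order %||% 3L,
    amplification = raw$amplification %||% 10)
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# materialise the component library a scenario refers to
scenario_library <- function(scenario) {
  grid <- wavelength_grid(scenario$grid$start_nm, scenario$grid$stop_nm,
                          scenario$grid$step_nm)
  params <- smoother_params(scenario$smoother$window_points,
                            scenario$smoother$poly_order)
  if (identical(scenario$library, "builtin")) {
    builtin_component_library(grid, params, scenario$amplification)
  } else {
    comps <- read_component_library(scenario$library)
    structure(list(components = comps, grid = grid, params = params,
                   amplification = scenario$amplification,
                   crossings = NULL),
              class = "component_library")
  }
}

#' Generate a seeded fixture set for a scenario
#'
#' Writes spectrum CSVs emulating the bench preparations: the NCT standard
#' series (20-120 ug/mL, 6 levels), the TRT standard series (0.5-5.0
#' ug/mL, 10 levels), the nominal mixture, and - for solution/cream
#' scenarios - the formulation A series (matrix + NCT + TRT with 0, 50,
#' 100, 150% standard additions) and B series (matrix + TRT additions
#' only). A `manifest.csv` records every file's nominal concentrations.
#' The same scenario and seed always reproduce identical file bytes.
#'
#' @param scenario A [scenario_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
fixture_generator <- function(scenario, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("fixture_generator: cannot create output directory ", out_dir,
           call. = FALSE)
    }
  }
  lib <- scenario_library(scenario)
  comps <- lib$components
  grid <- lib$grid
  sigma <- scenario$noise$sigma_AU
  seed0 <- scenario$noise$seed
  bg <- if (scenario$formulation == "pure") NULL
  else paste0(scenario$formulation, "_excipient")

  manifest <- list()
  idx <- 0L
  emit <- function(file, sample) {
    idx <<- idx + 1L
    s <- mix_spectrum(sample, comps, grid)
    if (sigma > 0) s <- add_noise(s, noise_model(sigma, seed0 + idx))
    write_spectrum_csv(s, file.path(out_dir, file))
    row <- data.frame(file = file,
                      NCT = if ("NCT" %in% names(sample))
                        sample[["NCT"]] else 0,
                      TRT = if ("TRT" %in% names(sample))
                        sample[["TRT"]] else 0,
                      matrix = if (any(endsWith(names(sample),
                                                "_excipient")))
                        scenario$formulation else "none")
    manifest[[idx]] <<- row
  }

  for (cc in c(20, 40, 60, 80, 100, 120)) {
    emit(sprintf("nct_standard_%03d.csv", cc), c(NCT = cc))
  }
  for (cc in seq(0.5, 5, by = 0.5)) {
    emit(sprintf("trt_standard_%04.1f.csv", cc), c(TRT = cc))
  }
  mixture <- unlist(scenario$mixture)
  emit("mixture.csv", mixture)

  if (!is.null(bg)) {
    adds <- c(0, 50, 100, 150)
    nct_fin <- c(40, 60, 80, 100)
    trt_fin <- c(1.0, 1.5, 2.0, 2.5)
    for (i in seq_along(adds)) {
      emit(sprintf("%s_A_add%03d.csv", scenario$formulation, adds[i]),
           stats::setNames(c(nct_fin[i], trt_fin[i], 1),
                           c("NCT", "TRT", bg)))
      emit(sprintf("%s_B_add%03d.csv", scenario$formulation, adds[i]),
           stats::setNames(c(trt_fin[i], 1), c("TRT", bg)))
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write / read an assay configuration as YAML
#'
#' Serialises every channel (analyte, wavelength, order, applicability)
#' with its calibration curve, plus the shared smoother settings.
#'
#' @param config A `"binary_assay_config"`.
#' @param path File path.
#' @return `write_assay_config` returns `path` invisibly;
#'   `read_assay_config` the restored configuration.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "binary_assay_config"))
  ser_curve <- function(cv) {
    if (is.null(cv)) return(NULL)
    cv[c("wavelength_nm", "deriv_order", "slope", "intercept", "r2",
         "residual_sd", "range_low", "range_high", "n_levels")]
  }
  ser_ch <- function(ch) {
    list(wavelength_nm = ch$wavelength_nm, order = ch$order,
         label = ch$label, nominal_nm = ch$nominal_nm,
         applicable = ch$applicable, curve = ser_curve(ch$curve))
  }
  yaml::write_yaml(list(
    smoother = unclass(config$params),
    amplification = config$amplification,
    nct_channels = lapply(config$nct_channels, ser_ch),
    trt_channel = ser_ch(config$trt_channel)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_assay_config
#' @export
read_assay_config <- function(path) {
  raw <- yaml::read_yaml(path)
  de_curve <- function(cv) {
    if (is.null(cv)) return(NULL)
    structure(cv, class = "calibration_curve")
  }
  de_ch <- function(ch) {
    assay_channel(ch$wavelength_nm %||% NA_real_, ch$order,
                  de_curve(ch$curve), label = ch$label,
                  nominal_nm = ch$nominal_nm,
                  applicable = isTRUE(ch$applicable))
  }
  binary_assay_config(
    lapply(raw$nct_channels, de_ch), de_ch(raw$trt_channel),
    smoother_params(raw$smoother$window_points, raw$smoother$poly_order),
    raw$amplification)
}
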