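#' Validation study configuration
#'
#' Settings for the seeded simulation studies that mirror an ICH-style
#' bench validation: accuracy, precision, specificity and robustness.
#'
#' @param library A `"component_library"`.
#' @param formulation Matrix the assay is validated against (`"pure"`,
#'   `"solution"`, `"cream"`).
#' @param nct_concs Accuracy/precision NCT levels (ug/mL); the paired TRT
#'   level is `nct * trt_over_nct` (the 1:40 mixture).
#' @param trt_over_nct TRT:NCT concentration ratio of the study mixtures.
#' @param replicates Repetitions per concentration (>= 2).
#' @param days Days for the inter-day precision arm.
#' @param sigma_AU Absorbance noise SD used in the studies. The default
#'   3e-6 AU places the noisiest derivative channels in the ~0.5-1.5% RSD
#'   band (see the methods vignette for this simulator calibration).
#' @param day_effect_sd SD of the multiplicative day-to-day response shift
#'   (default 0.5%); day 1 is the reference day.
#' @param seed Integer master seed; every study is bit-reproducible
#'   under it.
#' @param ratios Specificity grid: data.frame with `label` and `trt_conc`
#'   at fixed NCT 80 ug/mL.
#' @param specificity_nct NCT level held fixed in the specificity sweep.
#' @param robustness List of perturbation deltas: `noise_mult` (scan-speed
#'   proxy), `scan_range` (length-2 nm vector or `NULL`),
#'   `bandwidth_sd` (nm, Gaussian slit kernel).
#' @return A `"validation_config"` object.
#' @export
validation_config <- function(library,
                              formulation = "pure",
                              nct_concs = c(30, 60, 90),
                              trt_over_nct = 1 / 40,
                              replicates = 3L,
                              days = 3L,
                              sigma_AU = 3e-6,
                              day_effect_sd = 0.005,
                              seed = 1L,
                              ratios = data.frame(
                                label = c("1:40", "1:20", "1:27",
                                          "1:80", "1:160"),
                                trt_conc = c(2, 4, 3, 1, 0.5)),
                              specificity_nct = 80,
                              robustness = list(noise_mult = 3,
                                                scan_range = c(190, 350),
                                                bandwidth_sd = 1.0)) {
  stopifnot(inherits(library, "component_library"))
  if (replicates < 2L) {
    stop("validation_config: replicates must be >= 2", call. = FALSE)
  }
  if (any(ratios$trt_conc <= 0)) {
    stop("validation_config: specificity ratios must be > 0", call. = FALSE)
  }
  structure(list(library = library, formulation = formulation,
                 nct_concs = nct_concs, trt_over_nct = trt_over_nct,
                 replicates = as.integer(replicates), days = as.integer(days),
                 sigma_AU = sigma_AU, day_effect_sd = day_effect_sd,
                 seed = as.integer(seed), ratios = ratios,
                 specificity_nct = specificity_nct,
                 robustness = robustness),
            class = "validation_config")
}

rsd_percent <- function(x) {
  if (length(x) < 2L) return(0)
  s <- stats::sd(x)
  if (s == 0) 0 else 100 * s / mean(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# simulate one mixture measurement and assay it; returns the assay table
simulate_assay_once <- function(config, assay_cfg, nct, trt,
                                sigma = config$sigma_AU, scale = 1,
                                bandwidth_sd = 0) {
  comps <- config$library$components
  grid <- config$library$grid
  sample <- c(NCT = nct, TRT = trt)
  if (config$formulation != "pure") {
    bg <- paste0(config$formulation, "_excipient")
    sample <- c(sample, stats::setNames(1, bg))
  }
  s <- mix_spectrum(sample, comps, grid)
  if (scale != 1) s <- new_spectrum(grid, scale * s$absorbance, s$meta)
  if (bandwidth_sd > 0) s <- apply_bandwidth(s, bandwidth_sd)
  if (sigma > 0) s <- add_noise(s, noise_model(sigma))
  assay_binary_mixture(s, assay_cfg, nominal = c(NCT = nct, TRT = trt))
}

summarise_recoveries <- function(rows, study, condition) {
  parts <- split(rows, list(rows$channel, rows$analyte), drop = TRUE)
  out <- lapply(parts, function(p) {
    r <- p$recovery
    data.frame(study = study, condition = condition,
               channel = p$channel[1], analyte = p$analyte[1],
               n = sum(!is.na(r)),
               mean_recovery = mean(r), rsd = rsd_percent(r),
               min = min(r), max = max(r))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$analyte, out$channel), , drop = FALSE]
}

#' Accuracy study
#'
#' For each concentration level and replicate, simulates a noisy 1:40
#' mixture, assays every channel and reports mean recovery, RSD and range
#' per level plus a pooled row per channel. Fully seeded.
#'
#' @param config A [validation_config()] with at least 2 levels.
#' @param assay_cfg Optional pre-built `"binary_assay_config"`; built from
#'   the library when omitted.
#' @return Recovery table: `study`, `condition`, `channel`, `analyte`,
#'   `n`, `mean_recovery`, `rsd`, `min`, `max`.
#' @export
accuracy_study <- function(config, assay_cfg = NULL) {
  stopifnot(inherits(config, "validation_config"))
  if (length(config$nct_concs) < 2L) {
    stop("accuracy_study: need at least 2 concentrations", call. = FALSE)
  }
  if (is.null(assay_cfg)) {
    assay_cfg <- build_assay_config(config$library, config$formulation)
  }
  with_seed(config$seed + 101L, {
    all_rows <- list()
    for (cn in config$nct_concs) {
      rows <- do.call(rbind, lapply(seq_len(config$replicates), function(i)
        simulate_assay_once(config, assay_cfg, cn,
                            cn * config$trt_over_nct)))
      rows <- rows[!is.na(rows$recovery), , drop = FALSE]
      all_rows[[as.character(cn)]] <- rows
    }
    per_level <- do.call(rbind, lapply(names(all_rows), function(cn)
      summarise_recoveries(all_rows[[cn]], "accuracy",
                           paste0(cn, " ug/mL"))))
    pooled <- summarise_recoveries(do.call(rbind, all_rows), "accuracy",
                                   "pooled")
    out <- rbind(per_level, pooled)
    rownames(out) <- NULL
    out
  })
}

#' Precision study (intraday and inter-day)
#'
#' Day 1 replicates give the intraday repeatability; later days re-measure
#' the same design with fresh noise and a seeded multiplicative day shift
#' (intermediate precision). Reports the RSD per channel for each day
#' category and pooled across all days.
#'
#' @param config A [validation_config()] with `days >= 1`.
#' @param assay_cfg Optional pre-built assay configuration.
#' @return Recovery table as in [accuracy_study()]; conditions are
#'   `"intraday"`, `"inter-day 24 h"`, `"inter-day 48 h"`, ... and
#'   `"total"`.
#' @export
precision_study <- function(config, assay_cfg = NULL) {
  stopifnot(inherits(config, "validation_config"))
  if (config$days < 1L) stop("precision_study: days must be >= 1",
                             call. = FALSE)
  if (is.null(assay_cfg)) {
    assay_cfg <- build_assay_config(config$library, config$formulation)
  }
  with_seed(config$seed + 202L, {
    day_rows <- vector("list", config$days)
    for (d in seq_len(config$days)) {
      scale <- if (d == 1L) 1 else 1 + stats::rnorm(1, 0,
                                                    config$day_effect_sd)
      rows <- do.call(rbind, lapply(config$nct_concs, function(cn)
        do.call(rbind, lapply(seq_len(config$replicates), function(i)
          simulate_assay_once(config, assay_cfg, cn,
                              cn * config$trt_over_nct, scale = scale)))))
      day_rows[[d]] <- rows[!is.na(rows$recovery), , drop = FALSE]
    }
    labels <- c("intraday",
                if (config$days > 1L)
                  sprintf("inter-day %d h", 24L * seq_len(config$days - 1L)))
    per_day <- do.call(rbind, lapply(seq_len(config$days), function(d)
      summarise_recoveries(day_rows[[d]], "precision", labels[d])))
    total <- summarise_recoveries(do.call(rbind, day_rows), "precision",
                                  "total")
    out <- rbind(per_day, total)
    rownames(out) <- NULL
    out
  })
}

#' Specificity study
#'
#' Noiseless assays of the binary mixture at NCT 80 ug/mL across a grid of
#' TRT:NCT ratios; a final `"range"` row per channel reports the min-max
#' recovery over the sweep, the operational statement that the analyte
#' result is invariant to the interferent level.
#'
#' @param config A [validation_config()] with a non-empty ratio grid.
#' @param assay_cfg Optional pre-built assay configuration.
#' @return Recovery table; one row per (ratio, channel) plus range rows.
#' @export
specificity_study <- function(config, assay_cfg = NULL) {
  stopifnot(inherits(config, "validation_config"))
  if (nrow(config$ratios) == 0L) {
    stop("specificity_study: empty ratio grid", call. = FALSE)
  }
  if (is.null(assay_cfg)) {
    assay_cfg <- build_assay_config(config$library, config$formulation)
  }
  rows <- lapply(seq_len(nrow(config$ratios)), function(i) {
    res <- simulate_assay_once(config, assay_cfg, config$specificity_nct,
                               config$ratios$trt_conc[i], sigma = 0)
    res <- res[!is.na(res$recovery), , drop = FALSE]
    cbind(condition = config$ratios$label[i], res)
  })
  flat <- do.call(rbind, rows)
  per_ratio <- data.frame(study = "specificity", condition = flat$condition,
                          channel = flat$channel, analyte = flat$analyte,
                          n = 1L, mean_recovery = flat$recovery, rsd = 0,
                          min = flat$recovery, max = flat$recovery)
  range_rows <- summarise_recoveries(flat, "specificity", "range")
  out <- rbind(per_ratio, range_rows)
  rownames(out) <- NULL
  out
}

#' Robustness study
#'
#' Re-runs calibration and assay of the 1:40 mixture (NCT 80, TRT 2
#' ug/mL) at the 245 nm D2 channel and the 348 nm TRT channel under small
#' deliberate instrumental changes:
#'
#' * `scan_speed` - a noise-level multiplier (faster scanning integrates
#'   less light, hence more photometric noise);
#' * `scan_range` - the wavelength window is changed (default 190-350
#'   nm) and the whole pipeline re-run on the truncated grid; a channel
#'   whose wavelength falls off the new grid is flagged `"channel lost"`;
#' * `bandwidth` - spectra (standards and samples alike) are convolved
#'   with a Gaussian slit kernel, which shifts the interferent's
#'   zero-crossing; the assay insists on the unperturbed wavelengths, the
#'   strict reading of a zero-crossing method, so the NCT channel degrades
#'   while the broad-band TRT channel does not.
#'
#' @param config A [validation_config()]; `config$robustness` holds the
#'   deltas. `NULL` entries (or `noise_mult = 1`, `bandwidth_sd = 0`)
#'   reproduce the baseline.
#' @return Recovery table with a `"baseline"` condition and one condition
#'   per perturbation; lost channels carry `NA` statistics and a note in
#'   the `condition` string.
#' @export
robustness_study <- function(config) {
  stopifnot(inherits(config, "validation_config"))
  rb <- config$robustness
  assay_cfg <- build_assay_config(config$library, config$formulation)
  nct0 <- 80
  trt0 <- 2

  keep_channels <- function(res) {
    res[(res$analyte == "NCT" & res$deriv_order == 2L &
           !is.na(res$wavelength_nm) &
           abs(res$wavelength_nm - 245) <= 2) |
          res$analyte == "TRT", , drop = FALSE]
  }
  run_reps <- function(cfg2, sigma, bandwidth_sd = 0, config2 = config) {
    do.call(rbind, lapply(seq_len(config$replicates), function(i)
      keep_channels(simulate_assay_once(config2, cfg2, nct0, trt0,
                                        sigma = sigma,
                                        bandwidth_sd = bandwidth_sd))))
  }

  with_seed(config$seed + 303L, {
    out <- list(summarise_recoveries(run_reps(assay_cfg, config$sigma_AU),
                                     "robustness", "baseline"))

    mult <- if (is.null(rb$noise_mult)) 1 else rb$noise_mult
    out <- c(out, list(summarise_recoveries(
      run_reps(assay_cfg, mult * config$sigma_AU),
      "robustness", "scan_speed")))

    if (!is.null(rb$scan_range)) {
      g0 <- config$library$grid
      grid2 <- wavelength_grid(rb$scan_range[1], rb$scan_range[2],
                               g0$step_nm)
      lost <- c(`245/D2` = !(245 >= grid2$start_nm + 2 &
                               245 <= grid2$stop_nm - 2),
                `348/D0` = !(348 >= grid2$start_nm + 2 &
                               348 <= grid2$stop_nm - 2))
      if (any(lost)) {
        out <- c(out, list(data.frame(
          study = "robustness",
          condition = paste0("scan_range: channel lost (",
                             paste(names(lost)[lost], collapse = ", "), ")"),
          channel = names(lost)[lost],
          analyte = ifelse(names(lost)[lost] == "348/D0", "TRT", "NCT"),
          n = 0L, mean_recovery = NA_real_, rsd = NA_real_,
          min = NA_real_, max = NA_real_)))
      } else {
        lib2 <- config$library
        lib2$grid <- grid2
        cfg2 <- build_assay_config(lib2, config$formulation)
        config2 <- config
        config2$library <- lib2
        out <- c(out, list(summarise_recoveries(
          run_reps(cfg2, config$sigma_AU, config2 = config2),
          "robustness", "scan_range")))
      }
    }

    bw <- if (is.null(rb$bandwidth_sd)) 0 else rb$bandwidth_sd
    cfg_bw <- if (bw > 0) {
      recalibrate_under_bandwidth(config$library, assay_cfg, bw)
    } else assay_cfg
    out <- c(out, list(summarise_recoveries(
      run_reps(cfg_bw, config$sigma_AU, bandwidth_sd = bw),
      "robustness", "bandwidth")))

    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# re-fit the channel calibrations from standards measured under the slit
# kernel, holding the working wavelengths at their unperturbed values
recalibrate_under_bandwidth <- function(library, assay_cfg, sd_nm,
                                        nct_levels = c(20, 40, 60, 80,
                                                       100, 120),
                                        trt_levels = seq(0.5, 5, 0.5)) {
  comps <- library$components
  grid <- library$grid
  refit <- function(ch, model, levels) {
    if (!ch$applicable) return(ch)
    sig <- vapply(levels, function(cc) {
      s <- apply_bandwidth(component_spectrum(model, cc, grid), sd_nm)
      if (ch$order == 0L) signal_at(s, ch$wavelength_nm)
      else signal_at(derivative_spectrum(s, ch$order, assay_cfg$params,
                                         assay_cfg$amplification),
                     ch$wavelength_nm)
    }, 0)
    ch$curve <- fit_calibration(data.frame(concentration = levels,
                                           signal = sig),
                                ch$wavelength_nm, ch$order)
    ch
  }
  assay_cfg$nct_channels <- lapply(assay_cfg$nct_channels, refit,
                                   model = comps$NCT, levels = nct_levels)
  assay_cfg$trt_channel <- refit(assay_cfg$trt_channel, comps$TRT,
                                 trt_levels)
  assay_cfg
}

#' Run the full validation battery
#'
#' Accuracy, precision, specificity and robustness in one call, sharing
#' one assay configuration.
#'
#' @param config A [validation_config()].
#' @return Named list of recovery tables:
#'   `accuracy`, `precision`, `specificity`, `robustness`.
#' @export
run_validation_battery <- function(config) {
  assay_cfg <- build_assay_config(config$library, config$formulation)
  list(accuracy = accuracy_study(config, assay_cfg),
       precision = precision_study(config, assay_cfg),
       specificity = specificity_study(config, assay_cfg),
       robustness = robustness_study(config))
}
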