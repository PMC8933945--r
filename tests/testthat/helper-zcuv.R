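# shared, lazily built fixtures (the library build re-detects and verifies
# every zero-crossing, so build it once per test run)
.zcuv_test_cache <- new.env(parent = emptyenv())

shared_library <- function() {
  if (is.null(.zcuv_test_cache$lib)) {
    .zcuv_test_cache$lib <- builtin_component_library()
  }
  .zcuv_test_cache$lib
}

shared_assay_config <- function(formulation = "pure") {
  key <- paste0("cfg_", formulation)
  if (is.null(.zcuv_test_cache[[key]])) {
    .zcuv_test_cache[[key]] <- build_assay_config(shared_library(),
                                                  formulation)
  }
  .zcuv_test_cache[[key]]
}

# one-band test spectrum: Gaussian absorbance on a grid
gaussian_spectrum <- function(center, sigma, amp = 1,
                              grid = wavelength_grid(200, 400, 0.1)) {
  m <- component_model("g", list(gaussian_band(center, sigma, amp)))
  component_spectrum(m, 1, grid)
}

# analytic Gaussian derivatives for oracle comparisons
gauss_d1 <- function(l, c, s, a) -a * (l - c) / s^2 * exp(-(l - c)^2 / (2 * s^2))
gauss_d2 <- function(l, c, s, a) a * ((l - c)^2 - s^2) / s^4 * exp(-(l - c)^2 / (2 * s^2))

pure_mixture <- function(nct, trt, lib = shared_library()) {
  mix_spectrum(c(NCT = nct, TRT = trt), lib$components, lib$grid)
}

# independent signal-vs-concentration slope (simulate series, OLS)
response_slope_for_test <- function(model, wavelength, order, grid, params,
                                    amplification = 10,
                                    concs = c(20, 60, 100)) {
  sig <- vapply(concs, function(cc) {
    s <- component_spectrum(model, cc, grid)
    if (order == 0L) signal_at(s, wavelength)
    else signal_at(derivative_spectrum(s, order, params, amplification),
                   wavelength)
  }, 0)
  unname(stats::coef(stats::lm(sig ~ concs))[2])
}
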