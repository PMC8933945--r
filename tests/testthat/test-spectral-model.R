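test_that("component spectra obey Beer-Lambert linearity and additivity", {
  lib <- shared_library()
  grid <- lib$grid
  nct <- lib$components$NCT
  trt <- lib$components$TRT

  s0 <- component_spectrum(nct, 0, grid)
  expect_true(all(s0$absorbance == 0))

  s1 <- component_spectrum(nct, 40, grid)
  s2 <- component_spectrum(nct, 80, grid)
  expect_identical(s2$absorbance, 2 * s1$absorbance)

  # peak position of NCT at 80 ug/mL
  expect_equal(grid$wavelength[which.max(s2$absorbance)], 262,
               tolerance = 1 / 262)

  # TRT maximum near 348 nm
  st <- component_spectrum(trt, 2, grid)
  expect_equal(grid$wavelength[which.max(st$absorbance)], 348,
               tolerance = 1 / 348)

  # mixture = exact pointwise sum of components
  mx <- mix_spectrum(c(NCT = 40, TRT = 1), lib$components, grid)
  expect_identical(mx$absorbance,
                   component_spectrum(nct, 40, grid)$absorbance +
                     component_spectrum(trt, 1, grid)$absorbance)

  # empty mixture is all-zero
  empty <- mix_spectrum(stats::setNames(numeric(0), character(0)),
                        lib$components, grid)
  expect_true(all(empty$absorbance == 0))

  # degree-1 homogeneity at an awkward scale factor
  k <- 1.37
  expect_equal(component_spectrum(nct, k * 40, grid)$absorbance,
               k * s1$absorbance, tolerance = 1e-12)
})

test_that("NCT model has no absorbance above 300 nm", {
  lib <- shared_library()
  grid <- lib$grid
  for (conc in c(10, 80, 120)) {
    s <- component_spectrum(lib$components$NCT, conc, grid)
    peak <- max(s$absorbance)
    tail <- max(abs(s$absorbance[grid$wavelength > 310]))
    expect_lt(tail, 1e-6 * peak)
    expect_lt(abs(signal_at(s, 348)), 1e-9)
  }
  # hence the mixture equals the TRT-only spectrum past 310 nm
  mx <- pure_mixture(40, 1)
  trt_only <- component_spectrum(lib$components$TRT, 1, grid)
  hi <- grid$wavelength > 310
  expect_lt(max(abs(mx$absorbance[hi] - trt_only$absorbance[hi])), 1e-9)
})

test_that("spectral constructors validate their domains", {
  lib <- shared_library()
  grid <- lib$grid
  expect_error(gaussian_band(262, -1, 1), "sigma")
  expect_error(component_model("x", list(gaussian_band(262, 5, -1))),
               "background")
  expect_s3_class(component_model("bg", list(gaussian_band(262, 5, -1)),
                                  background = TRUE), "component_model")
  expect_error(component_spectrum(lib$components$NCT, -1, grid),
               "non-negative")
  expect_error(mix_spectrum(c(XXX = 1), lib$components, grid), "XXX")
  expect_error(wavelength_grid(400, 200, 0.1), "start")
  expect_error(wavelength_grid(200, 400, -0.1), "step")
  expect_error(wavelength_grid(200, 400.05, 0.1), "integer")
})

test_that("seeded noise is reproducible with the stated magnitude", {
  grid <- wavelength_grid(200, 400, 0.02)  # 10001 points
  s <- gaussian_spectrum(300, 20, 1, grid)

  expect_identical(add_noise(s, noise_model(0))$absorbance, s$absorbance)

  n1 <- add_noise(s, noise_model(0.002, seed = 42))
  n2 <- add_noise(s, noise_model(0.002, seed = 42))
  expect_identical(n1$absorbance, n2$absorbance)
  n3 <- add_noise(s, noise_model(0.002, seed = 43))
  expect_false(identical(n1$absorbance, n3$absorbance))

  # law of large numbers: realised SD within 5% of sigma_AU
  expect_equal(sd(n1$absorbance - s$absorbance), 0.002, tolerance = 0.05)

  # a seeded call must not perturb the session RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(add_noise(s, noise_model(0.002, seed = 9)))
  expect_identical(rnorm(3), before)
})

test_that("amplitude tuning matches the requested slopes and is linear", {
  lib <- shared_library()
  grid <- lib$grid
  params <- lib$params

  s348 <- response_slope_for_test(lib$components$TRT, 348, 0L, grid, params)
  expect_equal(s348, 0.1556, tolerance = 1e-4)
  lam253 <- lib$crossings$wavelength_nm[
    which.min(abs(lib$crossings$wavelength_nm - 253))]
  s253 <- response_slope_for_test(lib$components$NCT, lam253, 1L, grid,
                                  params)
  expect_equal(s253, 0.0068, tolerance = 1e-4)

  # scaling a tuned model's amplitudes by k multiplies its slope by k
  scaled <- lib$components$TRT
  scaled$bands <- lapply(scaled$bands, function(b) {
    b$amplitude <- 3 * b$amplitude
    b
  })
  expect_equal(response_slope_for_test(scaled, 348, 0L, grid, params),
               3 * s348, tolerance = 1e-10)

  # structurally dead channel is an error (NCT has no response at 348 nm)
  expect_error(
    tune_band_amplitudes(lib$components,
                         data.frame(component = "NCT",
                                    wavelength_nm = 348, order = 0L,
                                    slope = 0.1),
                         grid, params),
    "no structural response")

  # inconsistent multi-targets under a shape-preserving scale are rejected
  expect_error(
    tune_band_amplitudes(lib$components,
                         data.frame(component = c("TRT", "TRT"),
                                    wavelength_nm = c(348, 348),
                                    order = c(0L, 0L),
                                    slope = c(0.1556, 0.2)),
                         grid, params),
    "inconsistent")
})

test_that("component libraries round-trip through YAML", {
  lib <- shared_library()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_component_library(lib$components, path)
  back <- read_component_library(path)
  expect_setequal(names(back), names(lib$components))
  for (nm in names(back)) {
    expect_equal(absorptivity(back[[nm]], c(245, 262, 269, 348)),
                 absorptivity(lib$components[[nm]], c(245, 262, 269, 348)),
                 tolerance = 1e-12)
    expect_identical(back[[nm]]$background, lib$components[[nm]]$background)
  }
})

test_that("the bandwidth kernel broadens a Gaussian band analytically", {
  grid <- wavelength_grid(200, 400, 0.1)
  s <- gaussian_spectrum(300, 5, 1, grid)
  expect_identical(apply_bandwidth(s, 0)$absorbance, s$absorbance)
  out <- apply_bandwidth(s, 1.5)
  sig2 <- sqrt(5^2 + 1.5^2)
  expected <- (5 / sig2) * exp(-(grid$wavelength - 300)^2 / (2 * sig2^2))
  expect_equal(out$absorbance, expected, tolerance = 1e-4)
})
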