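test_that("the finite-difference oracle reproduces closed forms", {
  grid <- wavelength_grid(200, 400, 0.1)
  wl <- grid$wavelength
  inner <- 3:(length(wl) - 2)

  ramp <- new_spectrum(grid, 0.01 * wl + 2, list())
  d1 <- finite_difference_oracle(ramp, 1)
  expect_equal(d1$values[inner], rep(0.01, length(inner)),
               tolerance = 1e-9)

  quad <- new_spectrum(grid, 3e-5 * wl^2, list())
  d2 <- finite_difference_oracle(quad, 2)
  expect_equal(d2$values[inner], rep(6e-5, length(inner)),
               tolerance = 1e-6)

  # Gaussian band: central differences match the analytic derivative
  # to second order in the step
  s <- gaussian_spectrum(300, 8, 1, grid)
  a1 <- gauss_d1(wl, 300, 8, 1)
  a2 <- gauss_d2(wl, 300, 8, 1)
  f1 <- finite_difference_oracle(s, 1)$values
  f2 <- finite_difference_oracle(s, 2)$values
  expect_lt(max(abs(f1[inner] - a1[inner])), 10 * 0.1^2 * max(abs(a1)))
  expect_lt(max(abs(f2[inner] - a2[inner])), 10 * 0.1^2 * max(abs(a2)))

  tiny <- new_spectrum(wavelength_grid(200, 200.2, 0.1), c(1, 2, 3), list())
  expect_error(finite_difference_oracle(tiny, 2), "points")
})

test_that("Savitzky-Golay agrees with the oracle on smooth noiseless bands", {
  grid <- wavelength_grid(200, 400, 0.1)
  s <- gaussian_spectrum(300, 15, 1, grid)
  params <- smoother_params()
  inner <- 50:1950
  for (ord in 1:2) {
    sg <- derivative_spectrum(s, ord, params, amplification = 1)
    fd <- finite_difference_oracle(s, ord)
    peak <- max(abs(fd$values[inner]))
    expect_lt(max(abs(sg$values[inner] - fd$values[inner])), 1e-3 * peak)
  }
})

test_that("the derivative operator is linear and kills constants", {
  grid <- wavelength_grid(200, 400, 0.1)
  params <- smoother_params()
  inner <- 20:1980

  const <- new_spectrum(grid, rep(0.7, length(grid$wavelength)), list())
  for (ord in 1:2) {
    expect_lt(max(abs(derivative_spectrum(const, ord,
                                          params)$values[inner])), 1e-12)
  }

  s1 <- gaussian_spectrum(260, 6, 0.8, grid)
  s2 <- gaussian_spectrum(330, 15, 0.3, grid)
  a <- 2.5; b <- -1.2
  combo <- new_spectrum(grid, a * s1$absorbance + b * s2$absorbance, list())
  for (ord in 1:2) {
    lhs <- derivative_spectrum(combo, ord, params)$values
    rhs <- a * derivative_spectrum(s1, ord, params)$values +
      b * derivative_spectrum(s2, ord, params)$values
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("derivative preconditions are enforced", {
  grid <- wavelength_grid(200, 202, 0.5)
  s <- new_spectrum(grid, rep(1, 5), list())
  expect_error(derivative_spectrum(s, 1), "window")
  expect_error(derivative_spectrum(gaussian_spectrum(300, 8), 3), "order")
  expect_error(smoother_params(14), "odd")
  expect_error(smoother_params(3, 3), "poly_order")
  expect_error(derivative_spectrum(gaussian_spectrum(300, 8), 2,
                                   smoother_params(15, 1)), "poly_order")
})

test_that("signal_at interpolates linearly and rejects out-of-range queries", {
  grid <- wavelength_grid(200, 400, 0.1)
  s <- gaussian_spectrum(300, 10, 2, grid)
  i <- 501
  expect_identical(signal_at(s, grid$wavelength[i]), s$absorbance[i])
  mid <- (grid$wavelength[i] + grid$wavelength[i + 1]) / 2
  expect_equal(signal_at(s, mid),
               (s$absorbance[i] + s$absorbance[i + 1]) / 2,
               tolerance = 1e-12)
  expect_equal(signal_at(s, 300), 2, tolerance = 1e-5)  # analytic peak
  expect_error(signal_at(s, 150), "range")
  expect_error(signal_at(s, 400.2), "range")
})

test_that("a symmetric band family has exactly one D1 crossing at its center", {
  grid <- wavelength_grid(200, 400, 0.1)
  m <- component_model("g", list(gaussian_band(300, 10, 0.05)))
  family <- lapply(c(1, 2, 3), function(cc)
    component_spectrum(m, cc, grid))
  cr <- find_common_zero_crossings(family, 1)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$wavelength_nm, 300, tolerance = 0.2 / 300)
  expect_error(find_common_zero_crossings(list(), 1), "non-empty")
  half <- gaussian_spectrum(300, 10, 1, wavelength_grid(200, 300, 0.1))
  expect_error(find_common_zero_crossings(list(family[[1]], half), 1),
               "mixed grids")
})

test_that("the TRT family exposes the published zero-crossings", {
  lib <- shared_library()
  cr <- lib$crossings
  d1 <- cr[cr$order == 1, ]
  d2 <- cr[cr$order == 2, ]
  expect_true(any(abs(d1$wavelength_nm - 253) <= 2))
  expect_true(any(abs(d2$wavelength_nm - 245) <= 2))
  expect_true(any(abs(d2$wavelength_nm - 269) <= 2))

  # D2 crossings persist for a single-concentration family (TRT 2 ug/mL)
  single <- list(component_spectrum(lib$components$TRT, 2, lib$grid))
  cr1 <- find_common_zero_crossings(single, 2, lib$params)
  expect_true(any(abs(cr1$wavelength_nm - 245) <= 2))
  expect_true(any(abs(cr1$wavelength_nm - 269) <= 2))
})

test_that("formulation backgrounds preserve or break crossings as designed", {
  lib <- shared_library()
  sol <- zcuv:::trt_family_crossings(lib$components, lib$grid, lib$params,
                                     10, 2L, formulation = "solution")
  expect_true(any(abs(sol$wavelength_nm - 245) <= 2))
  expect_true(any(abs(sol$wavelength_nm - 269) <= 2))
  sol1 <- zcuv:::trt_family_crossings(lib$components, lib$grid, lib$params,
                                      10, 1L, formulation = "solution")
  expect_true(any(abs(sol1$wavelength_nm - 253) <= 2))

  crm <- zcuv:::trt_family_crossings(lib$components, lib$grid, lib$params,
                                     10, 2L, formulation = "cream")
  expect_false(any(abs(crm$wavelength_nm - 245) <= 2))
  expect_true(any(abs(crm$wavelength_nm - 269) <= 2))
  crm1 <- zcuv:::trt_family_crossings(lib$components, lib$grid, lib$params,
                                      10, 1L, formulation = "cream")
  expect_true(any(abs(crm1$wavelength_nm - 253) <= 2))
})

test_that("working-wavelength selection maximises analyte response", {
  lib <- shared_library()
  d2 <- lib$crossings[lib$crossings$order == 2, ]
  cand <- d2[abs(d2$wavelength_nm - 245) <= 2 |
               abs(d2$wavelength_nm - 269) <= 2, ]
  nct_d2 <- derivative_spectrum(
    component_spectrum(lib$components$NCT, 10, lib$grid), 2, lib$params)
  picked <- select_working_wavelength(cand, nct_d2)
  # the tuned NCT model responds ~2.6x more strongly at 269 than 245
  expect_equal(picked$wavelength_nm, 269, tolerance = 2 / 269)
  expect_gt(abs(picked$analyte_value), 0)

  single <- cand[1, , drop = FALSE]
  expect_identical(select_working_wavelength(single, nct_d2)$wavelength_nm,
                   single$wavelength_nm)

  # exact tie in analyte magnitude -> lowest wavelength
  flat <- zcuv:::new_deriv(lib$grid, rep(1, length(lib$grid$wavelength)),
                           2L, 10)
  expect_equal(select_working_wavelength(cand, flat)$wavelength_nm,
               min(cand$wavelength_nm))

  expect_error(select_working_wavelength(cand[0, ], nct_d2), "empty")
})

test_that("mixture derivative at a common crossing equals the analyte's", {
  lib <- shared_library()
  cfg <- shared_assay_config()
  for (ch in cfg$nct_channels) {
    mx <- derivative_spectrum(pure_mixture(80, 2), ch$order, cfg$params)
    nct <- derivative_spectrum(
      component_spectrum(lib$components$NCT, 80, lib$grid), ch$order,
      cfg$params)
    tol <- zcuv:::crossing_tolerance(lib$components$NCT, lib$grid,
                                     lib$params, 10, ch$order)
    expect_lt(abs(signal_at(mx, ch$wavelength_nm) -
                    signal_at(nct, ch$wavelength_nm)), tol)
  }
})

test_that("Savitzky-Golay filters noise harder than raw differencing", {
  grid <- wavelength_grid(240, 280, 0.1)
  clean <- gaussian_spectrum(260, 6, 1, grid)
  params <- smoother_params()
  set.seed(77)
  at <- 255
  sg <- fd <- numeric(60)
  for (i in seq_len(60)) {
    noisy <- add_noise(clean, noise_model(0.002))
    sg[i] <- signal_at(derivative_spectrum(noisy, 1, params), at)
    fd[i] <- signal_at(finite_difference_oracle(noisy, 1,
                                                amplification = 10), at)
  }
  expect_lt(sd(sg), sd(fd))
})
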