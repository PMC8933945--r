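zero_noise_config <- function(seed = 5) {
  validation_config(shared_library(), sigma_AU = 0, day_effect_sd = 0,
                    seed = seed,
                    robustness = list(noise_mult = 1,
                                      scan_range = c(190, 350),
                                      bandwidth_sd = 0))
}

test_that("the whole battery collapses to 100% recovery without noise", {
  battery <- run_validation_battery(zero_noise_config())
  for (tab in battery) {
    ok <- is.finite(tab$mean_recovery)
    expect_true(all(abs(tab$mean_recovery[ok] - 100) < 1e-6))
    expect_true(all(tab$rsd[is.finite(tab$rsd)] < 1e-6))
  }
})

test_that("studies re-run bit-identically under a fixed seed", {
  vc <- validation_config(shared_library(), seed = 17)
  cfg <- shared_assay_config()
  expect_identical(accuracy_study(vc, cfg), accuracy_study(vc, cfg))
  expect_identical(precision_study(vc, cfg), precision_study(vc, cfg))
  vc2 <- validation_config(shared_library(), seed = 18)
  expect_false(identical(accuracy_study(vc, cfg),
                         accuracy_study(vc2, cfg)))
})

test_that("RSD uses the n-1 standard deviation over the mean", {
  expect_equal(zcuv:::rsd_percent(c(98, 100, 102)), 2)
  expect_equal(zcuv:::rsd_percent(c(5, 5, 5)), 0)
  expect_equal(zcuv:::rsd_percent(c(7)), 0)
})

test_that("accuracy pooled recovery stays in the 98-102% window", {
  vc <- validation_config(shared_library(), seed = 29)
  tab <- accuracy_study(vc, shared_assay_config())
  pooled <- tab[tab$condition == "pooled", ]
  expect_identical(nrow(pooled), 4L)
  expect_true(all(pooled$mean_recovery > 98 & pooled$mean_recovery < 102))
  expect_true(all(pooled$n == vc$replicates * length(vc$nct_concs)))
  # a single-concentration design still yields level + pooled rows
  vc1 <- validation_config(shared_library(), nct_concs = c(60, 90),
                           seed = 30)
  tab1 <- accuracy_study(vc1, shared_assay_config())
  expect_setequal(unique(tab1$condition),
                  c("60 ug/mL", "90 ug/mL", "pooled"))
})

test_that("the precision design pools 27 assays and orders the RSDs", {
  vc <- validation_config(shared_library(), seed = 31)
  tab <- precision_study(vc, shared_assay_config())
  total <- tab[tab$condition == "total", ]
  expect_true(all(total$n == 27))
  expect_setequal(unique(tab$condition),
                  c("intraday", "inter-day 24 h", "inter-day 48 h",
                    "total"))

  # with a day effect, inter-day spread dominates intraday in expectation
  pick <- function(t, cond, chan) {
    t$rsd[t$condition == cond & t$channel == chan]
  }
  intr <- tot <- numeric(5)
  for (i in 1:5) {
    t <- precision_study(validation_config(shared_library(),
                                           seed = 40 + i,
                                           day_effect_sd = 0.01),
                         shared_assay_config())
    intr[i] <- pick(t, "intraday", "253/D1")
    tot[i] <- pick(t, "total", "253/D1")
  }
  expect_gt(mean(tot), mean(intr))
})

test_that("specificity reproduces the ratio sweep at 100%", {
  tab <- specificity_study(zero_noise_config(), shared_assay_config())
  r40 <- tab[tab$condition == "1:40", ]
  expect_identical(nrow(r40), 4L)
  expect_true(all(abs(r40$mean_recovery - 100) < 1e-6))
  rng <- tab[tab$condition == "range", ]
  expect_true(all(rng$min > 99 & rng$max < 101))
  expect_true(all(rng$n == 5))
})

test_that("zero-delta robustness perturbations reproduce the baseline", {
  tab <- robustness_study(zero_noise_config())
  for (cond in c("scan_speed", "scan_range", "bandwidth")) {
    rows <- tab[tab$condition == cond, ]
    expect_identical(nrow(rows), 2L)
    expect_true(all(abs(rows$mean_recovery - 100) < 1e-6))
  }
})

test_that("a bandwidth change breaks the NCT channel but not TRT", {
  vc <- validation_config(shared_library(), sigma_AU = 0,
                          day_effect_sd = 0, seed = 6,
                          robustness = list(noise_mult = 1,
                                            scan_range = NULL,
                                            bandwidth_sd = 1.0))
  tab <- robustness_study(vc)
  bw <- tab[tab$condition == "bandwidth", ]
  nct_dev <- abs(bw$mean_recovery[bw$analyte == "NCT"] - 100)
  trt_dev <- abs(bw$mean_recovery[bw$analyte == "TRT"] - 100)
  expect_gt(nct_dev, 0.5)
  expect_lt(trt_dev, 0.1)
  expect_gt(nct_dev, 10 * trt_dev)
})

test_that("a scan range cut that drops a channel is flagged, not silent", {
  vc <- validation_config(shared_library(), sigma_AU = 0,
                          day_effect_sd = 0, seed = 7,
                          robustness = list(noise_mult = 1,
                                            scan_range = c(200, 330),
                                            bandwidth_sd = 0))
  tab <- robustness_study(vc)
  lost <- tab[grepl("channel lost", tab$condition), ]
  expect_identical(lost$channel, "348/D0")
  expect_true(all(is.na(lost$mean_recovery)))
})

test_that("validation configuration invariants are enforced", {
  expect_error(validation_config(shared_library(), replicates = 1),
               "replicates")
  expect_error(validation_config(shared_library(),
                                 ratios = data.frame(label = "x",
                                                     trt_conc = -1)),
               "> 0")
})
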