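test_that("Delta-17O anomaly is the offset from the terrestrial fractionation line", {
  expect_identical(delta17O_excess(0, 0, 0.52), 0)
  expect_identical(delta17O_excess(10.4, 20.0, 0.52), 0)
  # snow-like nitrate: d17O back-computed from printed means
  expect_equal(delta17O_excess(58.02, 66.0, 0.52), 23.7, tolerance = 1e-12)
  # linearity and the on-line identity for arbitrary points
  for (x in c(-30, -1, 0.3, 12, 66)) {
    expect_equal(delta17O_excess(0.52 * x, x, 0.52), 0, tolerance = 1e-12)
  }
  a <- delta17O_excess(3, 7) + delta17O_excess(5, 11)
  expect_equal(delta17O_excess(8, 18), a, tolerance = 1e-12)
  expect_error(delta17O_excess(NaN, 1), "non-finite")
})

test_that("mass-overlap offset coefficient matches direct arithmetic", {
  expect_equal(estimate_xcorr(4.856, 2.7, 21.56), 0.1, tolerance = 1e-9)
  expect_identical(estimate_xcorr(2.7, 2.7, 20), 0)
  expect_equal(estimate_xcorr(3.7, 2.7, 20), 0.05, tolerance = 1e-12)
  expect_error(estimate_xcorr(3.7, 2.7, 0, standard = "USGS-35"), "USGS-35")
})

test_that("delta-15N mass-overlap correction scales with the anomaly and round-trips", {
  # a +30 per mil anomaly inflates d15N by ~3 per mil at xcorr = 0.1
  expect_equal(correct_d15N_mass_overlap(3.0, 30, 0.1), 0.0, tolerance = 1e-12)
  expect_identical(correct_d15N_mass_overlap(5.0, 0, 0.1), 5.0)
  expect_equal(correct_d15N_mass_overlap(-1.0, 10, 0.1), -2.0, tolerance = 1e-12)
  # missing anomaly: value passed through
  expect_identical(correct_d15N_mass_overlap(4.2, NA_real_, 0.1), 4.2)
  # round trip: re-adding xcorr * D17O restores the input exactly
  set.seed(11)
  d15 <- rnorm(50, 0, 3); D17 <- runif(50, 0, 32)
  back <- correct_d15N_mass_overlap(d15, D17, 0.1) + 0.1 * D17
  expect_equal(back, d15, tolerance = 1e-12)
})

test_that("water-exchange correction inverts the two-component mixing exactly", {
  expect_identical(correct_d18O_water_exchange(12.3, -10, 0), 12.3)
  expect_equal(correct_d18O_water_exchange(10, 10, 0.13), 10, tolerance = 1e-12)
  expect_equal(correct_d18O_water_exchange(57.4, -10, 0.13), 67.47,
               tolerance = 0.01)
  # forward mixing of the recovered value reproduces the measurement
  set.seed(12)
  meas <- rnorm(40, 30, 20); w <- rnorm(40, -12, 2)
  out <- correct_d18O_water_exchange(meas, w, 0.13)
  expect_equal(0.87 * out + 0.13 * w, meas, tolerance = 1e-9)
  expect_error(correct_d18O_water_exchange(1, 0, 1), "f must be in")
})

test_that("apply_corrections flags samples lacking a measurable anomaly", {
  smp <- data.frame(sample_id = c("a", "b"), group = c("lake", "lake"),
                    d15N = c(1, 1), d18O = c(20, 20),
                    d17O = c(15.4, NA), no3_uM = 1, nh4_uM = 1)
  out <- apply_corrections(smp, correction_parameters(water_d18O = 0,
                                                      exchange_fraction = 0))
  expect_equal(out$D17O[1], 15.4 - 0.52 * 20, tolerance = 1e-12)
  expect_true(out$d15N_corrected_flag[1])
  expect_false(out$d15N_corrected_flag[2])
  expect_equal(out$d15N[2], 1)  # uncorrected d15N retained
})

test_that("linear calibration recovers standards and held-out references", {
  refs <- reference_standards()
  expect_true(all(c("USGS-32", "USGS-34", "USGS-35") %in% refs$standard_name))
  # identity run: raw equals reference
  run <- make_run_sheet(slope = 1, intercept = 0)
  run$raw_d15N[1:3] <- refs$d15N[match(c("USGS-34", "USGS-32", "USGS-35"),
                                       refs$standard_name)]
  cal <- calibrate_linear(run, "d15N", refs)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  # two standards define the line exactly
  run2 <- data.frame(run_id = "r", sample_id = c("s1", "s2", "u"),
                     role = c("standard", "standard", "unknown"),
                     standard_name = c("A", "B", ""),
                     raw_d15N = c(-0.8, 181, 5), raw_d18O = NA_real_,
                     raw_d17O = NA_real_)
  cal2 <- calibrate_linear(run2, "d15N", c(A = -1.8, B = 180))
  expect_equal(cal2$slope, 1, tolerance = 1e-9)
  expect_equal(cal2$intercept, -1, tolerance = 1e-9)
  # >2 standards on a noisy line: residuals sum to zero, held-out standard
  # recovered within the long-term d15N precision (0.7 per mil)
  set.seed(5)
  slope <- 1.015; icept <- -0.4
  run3 <- make_run_sheet()
  truth <- c(`USGS-34` = -1.8, `USGS-32` = 180, `USGS-35` = 2.7)
  run3$raw_d15N[1:3] <- (truth - icept) / slope + rnorm(3, 0, 0.05)
  cal3 <- calibrate_linear(run3, "d15N", truth[c("USGS-34", "USGS-32")])
  expect_equal(sum(cal3$residuals), 0, tolerance = 1e-9)
  expect_lt(abs(cal3$calibrated[3] - 2.7), 0.7)
  expect_error(calibrate_linear(run2, "d15N", c(A = -1.8)), ">= 2 standards")
  expect_error(calibrate_linear(run2, "d15N", c(A = 5, B = 5)), "distinct")
})

test_that("run-sheet reduction yields analysis-ready records", {
  refs <- reference_standards()
  truth15 <- c(`USGS-34` = -1.8, `USGS-32` = 180, `USGS-35` = 2.7)
  truth18 <- c(`USGS-34` = -27.9, `USGS-32` = 25.7, `USGS-35` = 57.5)
  run <- make_run_sheet()
  run$raw_d15N[1:3] <- (truth15 - (-0.5)) / 1.02
  run$raw_d18O[1:3] <- (truth18 - 0.3) / 0.99
  run$group <- c("", "", "", "inflow", "lake")
  out <- reduce_run(run, refs,
                    correction_parameters(water_d18O = 0, exchange_fraction = 0))
  expect_equal(nrow(out), 2L)
  expect_equal(out$group, c("inflow", "lake"))
  expect_equal(out$d15N, 1.02 * c(1, -2) - 0.5, tolerance = 1e-9)
  expect_false(any(out$d15N_corrected_flag))  # no d17O in this run
})
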