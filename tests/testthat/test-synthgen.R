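test_that("default group parameters encode the survey's printed statistics", {
  gp <- default_group_params()
  expect_named(gp, c("snow", "inflow", "lake"))
  # snow: anomaly mean/spread 23.7 +/- 5.6 via fraction x endmember + noise
  snow <- gp$snow
  ea <- 0.73428  # truncated-normal mean of N(0.75, 0.15) on [0, 1]
  expect_equal(ea * snow$atm_endmember[1], 23.7, tolerance = 0.01)
  expect_equal(ea * snow$atm_endmember[2], 66.0, tolerance = 0.02)
  expect_equal(snow$nh4_uM[1], 5.8)
  # lake anomaly mean ~5.3; inflow/lake ammonium identical at 0.9
  lake <- gp$lake
  expect_equal(lake$atm_fraction[1] * lake$atm_endmember[1], 5.3,
               tolerance = 0.01)
  expect_equal(gp$inflow$nh4_uM[1], 0.9)
  expect_equal(lake$nh4_uM[1], 0.9)
  expect_equal(gp$inflow$no3_uM, c(28.7, 16.78))
  expect_equal(lake$no3_uM, c(1.6, 2.2))
  expect_equal(gp$snow$d15N[1], 0.9)
  expect_equal(gp$inflow$d15N[1], -1.6)
  expect_equal(lake$d15N[1], 0.8)
})

test_that("group sampling is reproducible, schema-complete and respects bounds", {
  gp <- default_group_params()
  empty <- generate_group_samples(group_params("lake", 0, c(0, 1), c(1, 1),
                                               c(1, 1), c(0.2, 0.1),
                                               c(23.7, 66)), seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("sample_id", "group", "d15N", "d18O", "d17O", "D17O",
                        "no3_uM", "nh4_uM", "d15N_corrected_flag"))
  a <- generate_group_samples(gp$snow, seed = 99)
  b <- generate_group_samples(gp$snow, seed = 99)
  expect_identical(a, b)
  big <- generate_group_samples(gp$inflow, seed = 3)
  expect_true(all(big$no3_uM >= 0 & big$nh4_uM >= 0))
  # anomaly column equals the triple-oxygen definition by construction
  expect_equal(big$D17O, big$d17O - 0.52 * big$d18O, tolerance = 1e-9)
})

test_that("snow sampling reproduces the configured moments at n = 1000", {
  gp <- default_group_params()
  gp$snow$n <- 1000L
  x <- generate_group_samples(gp$snow, seed = 7)
  expect_equal(mean(x$D17O), 23.7, tolerance = 0.5 / 23.7)
  expect_equal(sd(x$D17O), 5.6, tolerance = 0.5 / 5.6)
  expect_equal(mean(x$d18O), 66.0, tolerance = 1 / 66)
})

test_that("the combined default survey shows the expected oxygen-tracer correlation", {
  survey <- generate_survey(seed = 1)
  expect_equal(nrow(survey), 12L + 17L + 12L)
  r2 <- tracer_redundancy_check(survey)$r_squared
  expect_gte(r2, 0.88)
  expect_lte(r2, 0.98)
  # generated tables satisfy the sample-record invariants end to end
  expect_true(all(survey$no3_uM >= 0))
  expect_equal(survey$D17O, survey$d17O - 0.52 * survey$d18O,
               tolerance = 1e-9)
})

test_that("mixture simulation has the collapsed model's moments", {
  src <- make_two_sources()
  p <- c(0.3, 0.7)
  sc <- mixture_scenario(p, src, residual_sd = c(d15N = 1, D17O = 2),
                         n = 1e5, seed = 61)
  X <- generate_mixture_samples(sc)
  mu <- sapply(src, function(s) s$means[c("d15N", "D17O")])
  om <- sapply(src, function(s) s$sds[c("d15N", "D17O")])
  m_true <- drop(mu %*% p)
  v_true <- drop(om^2 %*% p^2) + c(1, 2)^2
  for (j in 1:2) {
    se_mean <- sqrt(v_true[j] / nrow(X))
    expect_lt(abs(mean(X[[j]]) - m_true[j]), 3 * se_mean)
    se_var <- v_true[j] * sqrt(2 / (nrow(X) - 1))
    expect_lt(abs(var(X[[j]]) - v_true[j]), 3 * se_var)
  }
  # degenerate scenario collapses to the exact mixture mean
  d0 <- list(source_profile("a", c(d15N = 2), c(d15N = 0)),
             source_profile("b", c(d15N = 8), c(d15N = 0)))
  X0 <- generate_mixture_samples(
    mixture_scenario(c(0.5, 0.5), d0, residual_sd = c(d15N = 0),
                     n = 5, seed = 1, tracers = "d15N"))
  expect_equal(X0$d15N, rep(5, 5))
  # single-source proportions reproduce that source's distribution
  X1 <- generate_mixture_samples(
    mixture_scenario(c(1, 0), src, residual_sd = c(d15N = 0, D17O = 0),
                     n = 2e4, seed = 62))
  expect_equal(mean(X1$d15N), src[[1]]$means[["d15N"]], tolerance = 0.02)
  expect_equal(sd(X1$d15N), src[[1]]$sds[["d15N"]], tolerance = 0.02)
})
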