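test_that("end-tidal detection finds constant plateaus on triangular breaths", {
  # three triangular breaths 0 -> 40 -> 0 mmHg, 2 s each at 10 Hz
  one <- c(seq(0, 40, by = 4), seq(36, 4, by = -4))
  co2 <- rep(one, 3)
  tr <- capno_trace(time = (seq_along(co2) - 1) / 10, co2 = co2)
  et <- extract_end_tidal(tr, min_breath_period = 1,
                          baseline_window = c(0, 6))
  expect_equal(et$etco2, c(40, 40, 40))
})

test_that("detection equals the generator's ground truth for square plateaus", {
  sim <- quick_sim(tau = 0, seed = 3)
  et <- extract_end_tidal(sim$trace)
  expect_identical(et$time, sim$truth$time)
  expect_identical(et$etco2, sim$truth$etco2)
})

test_that("detection equals an exhaustive windowed-maximum search", {
  for (seed in 1:5) {
    rate <- c(10, 12, 15, 16, 18)[seed]
    sim <- quick_sim(tau = 3, seed = seed, plateau_noise = 0.5, rate = rate)
    et <- extract_end_tidal(sim$trace, min_breath_period = 2)
    oracle <- oracle_breath_maxima(sim$trace, 60 / rate)
    expect_equal(nrow(et), nrow(oracle))
    expect_equal(et$etco2, oracle$etco2)
    expect_equal(et$time, oracle$time)
  }
})

test_that("detection errors are informative", {
  expect_error(extract_end_tidal(capno_trace(0:100, rep(40, 101))),
               "constant")
  tr <- capno_trace(seq(0, 10, by = 0.1), 40 + sin(seq(0, 10, by = 0.1)))
  expect_error(extract_end_tidal(tr, prominence_fraction = 5),
               "prominence")
})

test_that("regressor interpolation matches hand calculations", {
  et <- manual_et(c(0, 10), c(40, 48), baseline_window = c(0, 5))
  reg <- build_regressor(et, sample_times = c(0, 2, 10))
  expect_equal(reg$raw_mmHg, c(40, 41.6, 48))
  expect_equal(attr(reg, "bulk_delay"), 0)

  # constant series: constant interpolant everywhere on the grid
  etc <- manual_et(seq(5, 355, by = 5), rep(40, 71))
  regc <- build_regressor(etc, seq(0, 357, by = 3))
  expect_equal(unique(regc$raw_mmHg), 40)

  # acquisition outside the support errors
  expect_error(build_regressor(et, sample_times = seq(0, 100, 2)),
               "outside the end-tidal series support")
})

test_that("cross-correlation alignment recovers a planted bulk delay", {
  sim <- quick_sim(tau = 5, seed = 4)
  times <- seq(0, 357, by = 3)
  shifted <- approx(sim$truth$time, sim$truth$etco2, xout = times - 6,
                    rule = 2)$y
  bold <- bold_series(times, 100 + shifted)
  reg <- build_regressor(sim$truth, times, bold_for_alignment = bold,
                         max_delay = 15, delay_step = 1)
  expect_equal(attr(reg, "bulk_delay"), 6)
})

test_that("normalization subtracts the baseline mean and divides by the max", {
  # constant series maps to all zeros
  expect_equal(as.numeric(normalize_etco2(rep(40, 5), 1:5, c(1, 5))),
               rep(0, 5))
  # hand arithmetic: 8/48
  n <- normalize_etco2(c(40, 40, 48, 48), 1:4, c(1, 2))
  expect_equal(as.numeric(n), c(0, 0, 8 / 48, 8 / 48), tolerance = 1e-12)
  # scale invariance under positive rescaling
  for (c_ in c(0.5, 3, 120)) {
    n2 <- normalize_etco2(c_ * c(40, 40, 48, 48), 1:4, c(1, 2))
    expect_equal(as.numeric(n2), as.numeric(n), tolerance = 1e-12)
  }
  # additive offset shifts by -c/max (equivariance)
  n3 <- normalize_etco2(c(40, 40, 48, 48) + 2, 1:4, c(1, 2))
  expect_equal(as.numeric(n3), c(0, 0, 8 / 50, 8 / 50), tolerance = 1e-12)
  expect_error(normalize_etco2(c(-1, -2), 1:2, c(1, 2)), "positive")
})

test_that("delta EtCO2 uses second-half CO2 breaths against the initial baseline", {
  par <- paradigm_spec()
  # planted step recovered exactly
  sim <- quick_sim(tau = 0, seed = 1)
  expect_equal(compute_delta_etco2(sim$truth, par), 8)

  # blocks at 48 and 50: mean of per-block means
  tms <- seq(2.5, 357.5, by = 5)
  blk <- findInterval(tms, par$start)
  vals <- c(40, 48, 40, 50, 40)[blk]
  expect_equal(compute_delta_etco2(manual_et(tms, vals), par), 9)

  # linear within-block ramp 44 -> 48 over 75 s: second-half mean 47
  # (breath times chosen symmetric about the second-half midpoint)
  tms2 <- seq(3.75, 358.75, by = 5)
  blk2 <- findInterval(tms2, par$start)
  ramp <- function(t, b) 44 + 4 * (t - par$start[b]) / 75
  vals2 <- ifelse(blk2 %in% c(2, 4), ramp(tms2, blk2), 40)
  expect_equal(compute_delta_etco2(manual_et(tms2, vals2), par), 7)

  # empty second-half window errors naming the block
  sparse <- manual_et(c(10, 30, 50, 70), c(40, 40, 40, 48))
  expect_error(compute_delta_etco2(sparse, par), "CO2 block 2")
})

test_that("trace QC flags steady-state and baseline-return violations", {
  par <- paradigm_spec()
  sim <- quick_sim(tau = 0, seed = 1)
  qc <- qc_trace(sim$truth, par)
  expect_true(qc_pass(qc))
  expect_true(all(qc$pass))
  expect_equal(nrow(qc), 4) # 2 steady-state + 2 baseline-return checks

  tms <- seq(2.5, 357.5, by = 5)
  blk <- findInterval(tms, par$start)

  # post-block baseline at 43 vs initial 40 with tolerance 2 fails
  vals <- c(40, 48, 43, 48, 43)[blk]
  qc2 <- qc_trace(manual_et(tms, vals), par, baseline_tolerance = 2)
  expect_false(qc_pass(qc2))
  expect_false(any(qc2$pass[qc2$check == "baseline_return"]))
  expect_equal(qc2$statistic[qc2$check == "baseline_return"][1], 3)

  # second-half slope 0.05 mmHg/s against tolerance 0.02 fails
  slope_vals <- ifelse(blk %in% c(2, 4),
                       48 + 0.05 * (tms - par$start[blk]), 40)
  qc3 <- qc_trace(manual_et(tms, slope_vals), par, slope_tolerance = 0.02)
  expect_false(all(qc3$pass[qc3$check == "steady_state"]))
  expect_equal(qc3$statistic[qc3$check == "steady_state"][1], 0.05,
               tolerance = 1e-9)
})

test_that("QC fails when the generator drifts its baseline", {
  # emulate a drifting baseline by shifting post-block plateaus upward
  par <- paradigm_spec()
  tms <- seq(2.5, 357.5, by = 5)
  blk <- findInterval(tms, par$start)
  vals <- c(40, 48, 44, 52, 47)[blk]
  expect_false(qc_pass(qc_trace(manual_et(tms, vals), par)))
})
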