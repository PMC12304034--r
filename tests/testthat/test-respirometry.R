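test_that("mass-balance arithmetic matches hand calculations", {
  expect_equal(compute_vco2(1000, 0.0005, 1000, 0.0005), 0)
  expect_equal(compute_vco2(1000, 0.002, 1000, 0), 2)
  expect_equal(compute_vco2(600, 0.0012, 600, 0.0004), 0.48)
  expect_warning(compute_vco2(1000, 0.0001, 1000, 0.0005), "baseline")
  expect_error(compute_vco2(0, 0.001, 1000, 0), "positive")
  expect_error(compute_vco2(1000, 0.2, 1000, 0), "0.05")
})

test_that("water-vapour conversion applies the vapour density", {
  expect_equal(compute_ewl(1000, 0.001, 1000, 0), 0.803)
  expect_equal(compute_ewl(1000, 0.001, 1000, 0, units = "g_h"),
               0.803 * 60 / 1000)
  expect_equal(compute_ewl(1000, 0.0007, 1000, 0.0007), 0)
  # linear in flow with fixed fractions
  expect_equal(compute_ewl(2000, 0.001, 2000, 0),
               2 * compute_ewl(1000, 0.001, 1000, 0))
})

test_that("energy conversions carry the standard constants", {
  expect_equal(vco2_to_watts(0), 0)
  expect_equal(vco2_to_watts(1), 27.8 / 60, tolerance = 1e-12)
  # inverse: 0.06 W corresponds to ~0.1295 ml CO2 per min
  expect_equal(0.06 / (27.8 / 60), 0.1295, tolerance = 1e-3)
  er <- ehl_and_ratio(1, 0.5)
  expect_equal(er$ehl_w, 2.406 * 1000 / 3600, tolerance = 1e-12)
  er0 <- ehl_and_ratio(0, 0.5)
  expect_equal(er0$ehl_w, 0); expect_equal(er0$ehl_mhp, 0)
  # printed summary-cell inputs: 0.38 g/h against 0.15 W
  er2 <- ehl_and_ratio(0.38, 0.15)
  expect_equal(er2$ehl_w, 0.2540, tolerance = 5e-4)
  expect_equal(er2$ehl_mhp, 1.69, tolerance = 1e-2)
  expect_warning(out <- ehl_and_ratio(0.5, 0), "undefined")
  expect_true(is.na(out$ehl_mhp))
})

test_that("unit chains round-trip to float tolerance", {
  g_h <- 0.38
  mg_min <- g_h * 1000 / 60
  expect_equal(mg_min * 60 / 1000, g_h, tolerance = 1e-12)
  w <- vco2_to_watts(0.73)
  expect_equal(w * 60 / 27.8, 0.73, tolerance = 1e-12)
})

test_that("RER scenarios compare by closed-form rescaling", {
  set.seed(2)
  physio <- data.frame(vco2 = runif(20, 0.1, 0.6))
  same <- rer_scenario_comparison(physio, c(default = 27.8))
  expect_equal(same$rmsd_w, 0)
  expect_equal(same$r_squared, 1)
  # scaling the joule equivalent by 1.05 is a pure rescale: R^2 stays 1 and
  # the RMSD has the closed form 0.05 * rms of the default conversion
  up <- rer_scenario_comparison(physio, c(up = 27.8 * 1.05))
  ref <- physio$vco2 * 27.8 / 60
  expect_equal(up$r_squared, 1, tolerance = 1e-12)
  expect_equal(up$rmsd_w, 0.05 * sqrt(mean(ref^2)), tolerance = 1e-12)
  # brute-force recomputation for two stated equivalents
  alts <- c(rer_075 = 27.54, rer_083 = 26.57)
  out <- rer_scenario_comparison(physio, alts)
  for (i in 1:2) {
    brute <- sqrt(mean((physio$vco2 * alts[i] / 60 - ref)^2))
    expect_equal(out$rmsd_w[i], brute, tolerance = 1e-12)
  }
  physio$vco2[3] <- NA
  expect_message(rer_scenario_comparison(physio, alts), "skipping 1")
})

test_that("stable-window selection finds the lowest stable period", {
  t5 <- seq(0, 1795, by = 5)
  # constant series: any window, mean equal to the constant
  w <- select_stable_window(t5, rep(2, length(t5)))
  expect_equal(w$mean, 2)
  expect_true(w$stable)
  # a flat valley at 1.0 inside a series at 3.0 is selected
  v <- rep(3, length(t5)); v[100:180] <- 1
  w2 <- select_stable_window(t5, v)
  expect_equal(w2$mean, 1)
  expect_gte(w2$start_s, t5[100]); expect_lte(w2$end_s, t5[180])
  # noisy plateau: selected mean within 2 SEM of the plateau value
  set.seed(5)
  noisy <- 2 + rnorm(length(t5), 0, 0.02)
  w3 <- select_stable_window(t5, noisy)
  expect_lt(abs(w3$mean - 2), 2 * 0.02 / sqrt(60))
  expect_error(select_stable_window(t5[1:10], rep(1, 10)), "shorter")
})

test_that("drift and lag correction restores the emitted signal", {
  ph <- data.frame(ta_set = c(28, 32, 36, 40),
                   vco2 = c(0.13, 0.15, 0.22, 0.35),
                   ewl_g_h = c(0.05, 0.07, 0.12, 0.25),
                   tsub = c(34.6, 35.2, 37.0, 40.1))
  # zero drift: correction is the identity on the chamber excess
  tr0 <- gen_raw_gas_trace(ph)
  cor0 <- correct_drift_lag(tr0, lag_s = 0)
  expect_equal(cor0$data$frac_co2, tr0$data$frac_co2, tolerance = 1e-12)
  # injected linear drift: corrected baseline bias below 1% of signal
  trd <- gen_raw_gas_trace(ph, drift_rate = 1e-5)
  cord <- correct_drift_lag(trd, lag_s = 0)
  base_idx <- cord$data$source == "baseline"
  resid <- cord$data$frac_co2[base_idx] - cord$frac_in["co2"]
  expect_lt(max(abs(resid)), 0.01 * (ph$vco2[1] / 1000))
  # injected 15-s lag recovered within one or two sampling steps
  trl <- gen_raw_gas_trace(ph, lag_s = 15)
  expect_lte(abs(estimate_lag(trl) - 15), 5)
})

test_that("reduction inverts the generator exactly without noise", {
  ph <- data.frame(ta_set = c(28, 32, 36, 40, 42),
                   vco2 = c(0.13, 0.14, 0.2, 0.35, 0.5),
                   ewl_g_h = c(0.05, 0.06, 0.1, 0.25, 0.38),
                   tsub = c(34.6, 35, 36.5, 40.5, 42))
  red <- reduce_trial(gen_raw_gas_trace(ph, flow_ml_min = 1000))
  expect_equal(red$vco2, ph$vco2, tolerance = 1e-9)
  expect_equal(red$waewl_g_h, ph$ewl_g_h, tolerance = 1e-9)
  expect_equal(red$tsub, ph$tsub, tolerance = 1e-9)
  expect_equal(red$warmr_w, ph$vco2 * 27.8 / 60, tolerance = 1e-9)
  # EHL/MHP exceeds 1 exactly when EHL exceeds metabolic heat production
  expect_equal(red$ehl_mhp > 1, red$ehl_w > red$warmr_w)
})

test_that("a trial terminated at 42 yields no 44-degC point", {
  ph <- data.frame(ta_set = c(28, 32, 36, 40, 42),
                   vco2 = c(0.1, 0.12, 0.15, 0.2, 0.3),
                   ewl_g_h = c(0.04, 0.05, 0.08, 0.15, 0.23),
                   tsub = c(34.6, 35, 36, 40, 42.6))
  red <- reduce_trial(gen_raw_gas_trace(
    ph, termination = list(ta = 42, reason = "behavioural")))
  expect_equal(red$ta_set, c(28, 32, 36, 40, 42))
  expect_false(44 %in% red$ta_set)
})

test_that("negative concentrations and disordered schedules are rejected", {
  ph <- data.frame(ta_set = 28, vco2 = 0.1, ewl_g_h = 0.05, tsub = 35)
  tr <- gen_raw_gas_trace(ph)
  bad <- tr$data; bad$frac_co2[5] <- -1e-4
  expect_error(resp_trial(bad, tr$schedule), "negative")
  expect_error(resp_trial(tr$data, data.frame(ta_set = c(32, 28),
                                              start_s = c(0, 100),
                                              end_s = c(50, 200))),
               "increasing")
})
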