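test_that("maximal sub-threshold runs become bouts under the strict rules", {
  # 20 degC for 60 min bounded by normothermic samples -> one 60-min bout
  v <- c(35, 35, rep(20, 7), 35, 35)
  b <- detect_torpor_bouts(mk_trace(v))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 60)
  expect_equal(b$min_tskin, 20)
  # a 27-degC dip lasting 20 min is not a bout ("more than 30 min")
  expect_equal(nrow(detect_torpor_bouts(mk_trace(c(35, 35, 27, 27, 27, 35)))), 0)
  # a span of exactly 30 min is still not a bout (strict inequality)
  expect_equal(nrow(detect_torpor_bouts(mk_trace(c(35, 35, 20, 20, 20, 20, 35)))), 0)
  # exactly at the threshold does not count as torpid (strict <)
  expect_equal(nrow(detect_torpor_bouts(mk_trace(c(35, rep(28, 8), 35)))), 0)
})

test_that("trace edges and recording gaps censor bouts", {
  # run touching the trace end
  b_end <- detect_torpor_bouts(mk_trace(c(35, 35, rep(20, 8))))
  expect_true(b_end$censored)
  # 40-min gap inside a cold run splits it into two censored fragments
  times <- t0_utc + c(0:5, 10:16) * 600
  tr <- telemetry_trace(data.frame(time = times,
                                   tskin = c(35, rep(20, 5), rep(20, 6), 35)))
  b <- detect_torpor_bouts(tr)
  expect_equal(nrow(b), 2)
  expect_true(all(b$censored))
  expect_error(detect_torpor_bouts(
    telemetry_trace(data.frame(time = t0_utc + 600, tskin = 20))),
    "at least 2")
})

test_that("arousal classification separates tracking from endogenous rises", {
  # passive: rewarming at ~0.1 degC/min while Ta rises at the same rate,
  # then a jump to normothermy
  ta <- data.frame(time = t0_utc + (0:30) * 600,
                   ta = 14 + pmax(0, (0:30) - 10) * 1)
  tskin <- c(rep(35, 3), rep(16, 8), 16 + (1:10) * 1, 35, 35, rep(35, 8))
  tr_p <- telemetry_trace(data.frame(time = t0_utc + seq_along(tskin) * 600 - 600,
                                     tskin = tskin), ta = ta)
  b_p <- classify_arousal(detect_torpor_bouts(tr_p), tr_p)
  expect_equal(b_p$arousal, "passive")
  # active: 1.2 degC/min against flat ambient
  ta_flat <- data.frame(time = t0_utc + (0:30) * 600, ta = rep(14, 31))
  tskin_a <- c(rep(35, 3), rep(16, 10), 28, 35, rep(35, 8))
  tr_a <- telemetry_trace(data.frame(time = t0_utc + seq_along(tskin_a) * 600 - 600,
                                     tskin = tskin_a), ta = ta_flat)
  b_a <- classify_arousal(detect_torpor_bouts(tr_a), tr_a)
  expect_equal(b_a$arousal, "active")
  # without an ambient series the label stays unclassified
  tr_n <- telemetry_trace(data.frame(time = t0_utc + seq_along(tskin_a) * 600 - 600,
                                     tskin = tskin_a))
  b_n <- classify_arousal(detect_torpor_bouts(tr_n), tr_n)
  expect_equal(b_n$arousal, "unclassified")
})

test_that("generator-labelled arousals are recovered above 90%", {
  plan <- mk_bout_plan(passive_days = 0:28, active_days = 0:10)
  sim <- gen_telemetry(telemetry_sim_config(30, bout_plan = plan,
                                            noise_sd = 0.3, seed = 17))
  b <- classify_arousal(detect_torpor_bouts(sim$trace), sim$trace)
  expect_equal(nrow(b), 40)
  agree <- mean(b$arousal == sim$truth$arousal)
  expect_gte(agree, 0.9)
})

test_that("a 61-bout season is detected exactly on a noiseless trace", {
  plan <- mk_bout_plan(passive_days = 0:32, active_days = 0:13,
                       passive_dur = 330, active_dur = 300)
  sim <- gen_telemetry(telemetry_sim_config(34, bout_plan = plan, seed = 1))
  expect_equal(nrow(sim$truth), 47)
  extra <- mk_bout_plan(passive_days = 33:46, active_days = integer())
  plan61 <- rbind(plan, extra)
  sim61 <- gen_telemetry(telemetry_sim_config(48, bout_plan = plan61, seed = 1))
  b <- detect_torpor_bouts(sim61$trace)
  expect_equal(nrow(b), 61)
  expect_equal(b$duration_min, sim61$truth$duration_sampled)
  s <- bout_statistics(b)
  cfg_mean <- mean(plan61$duration_min)
  expect_lt(abs(s$duration_mean - cfg_mean) / cfg_mean, 0.05)
})

test_that("pre-dawn entries are phased correctly", {
  plan <- mk_bout_plan(passive_days = 0:3, active_days = 1)
  sim <- gen_telemetry(telemetry_sim_config(5, bout_plan = plan, seed = 4))
  b <- detect_torpor_bouts(sim$trace)
  # passive bouts enter at 04:00 (within 120 min of the 06:00 sunrise)
  expect_equal(sum(b$entry_phase == "pre-dawn"), 4)
  expect_equal(sum(b$entry_phase == "day"), 1)
})

test_that("daily summaries compute the pooled arithmetic", {
  # two days with ranges [10,30] and [12,34]
  day1 <- rep(c(10, 30), each = 72)
  day2 <- rep(c(12, 34), each = 72)
  tr <- telemetry_trace(data.frame(time = t0_utc + (0:287) * 600,
                                   tskin = c(day1, day2)))
  s <- daily_summaries(tr)
  pooled <- s$pooled[s$pooled$variable == "tskin", ]
  expect_equal(pooled$mean_daily_max, 32)
  expect_equal(pooled$mean_daily_range, 21)
  expect_equal(pooled$abs_min, 10)
  expect_equal(pooled$abs_max, 34)
  # a single constant day collapses to zero range
  tr1 <- telemetry_trace(data.frame(time = t0_utc + (0:143) * 600,
                                    tskin = rep(25, 144)))
  s1 <- daily_summaries(tr1)
  expect_equal(s1$pooled$mean_daily_range, 0)
  expect_equal(s1$pooled$mean_daily_min, s1$pooled$mean_daily_max)
})

test_that("days with poor coverage are excluded", {
  # day 2 has only 20 samples (< 50% of 144)
  tt <- c(t0_utc + (0:143) * 600, t0_utc + 86400 + (0:19) * 600)
  tr <- telemetry_trace(data.frame(time = tt, tskin = rep(25, length(tt))))
  expect_message(s <- daily_summaries(tr), "coverage")
  expect_equal(s$pooled$n_days, 1)
})

test_that("bout statistics use the sample SD and respect censoring", {
  b <- detect_torpor_bouts(mk_trace(c(35, rep(20, 11), 35)))
  # hand-built bout table through the same class
  b3 <- b[c(1, 1, 1), ]
  b3$duration_min <- c(100, 200, 300)
  b3$censored <- FALSE
  s <- bout_statistics(b3)
  expect_equal(s$duration_mean, 200)
  expect_equal(s$duration_sd, 100)
  expect_equal(s$duration_longest, 300)
  # a single censored bout is counted but contributes no duration stats
  b1 <- b[1, ]; b1$censored <- TRUE
  s1 <- bout_statistics(b1)
  expect_equal(s1$n_bouts, 1)
  expect_true(is.na(s1$duration_mean))
})

test_that("bouts are disjoint, bounded by the trace, and stable to finer sampling", {
  plan <- mk_bout_plan(passive_days = 0:5, active_days = 0:2)
  for (interval in c(10, 5)) {
    sim <- gen_telemetry(telemetry_sim_config(7, bout_plan = plan,
                                              sample_interval = interval,
                                              seed = 8))
    b <- detect_torpor_bouts(sim$trace)
    expect_equal(nrow(b), 9)
    expect_true(all(diff(as.numeric(b$start)) > 0))
    # pairwise disjoint and inside the trace span
    expect_true(all(as.numeric(b$start[-1]) > as.numeric(b$end[-nrow(b)])))
    span <- diff(range(as.numeric(sim$trace$samples$time))) / 60
    expect_lte(sum(b$duration_min), span)
  }
})

test_that("telemetry CSV round-trips", {
  sim <- gen_telemetry(telemetry_sim_config(
    2, bout_plan = mk_bout_plan(0, integer()), seed = 2))
  path <- tempfile(fileext = ".csv")
  write_telemetry_csv(sim$trace, path)
  back <- read_telemetry_csv(path)
  expect_equal(back$samples$tskin, sim$trace$samples$tskin, tolerance = 1e-9)
  expect_equal(as.numeric(back$samples$time), as.numeric(sim$trace$samples$time))
})
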