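# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

t0_utc <- as.POSIXct("2022-12-01 00:00:00", tz = "UTC")

# Trace from a plain Tskin vector at 10-min spacing.
mk_trace <- function(tskin, interval_min = 10, ta = NULL) {
  times <- t0_utc + seq_along(tskin) * interval_min * 60
  telemetry_trace(data.frame(time = times, tskin = tskin), ta = ta)
}

# Bout plan mixing pre-dawn passive bouts and evening active bouts.
# Passive: enter 04:00, cross the threshold mid-morning. Active: enter
# 19:00 while ambient is falling, cross at midnight.
mk_bout_plan <- function(passive_days, active_days,
                         passive_dur = 330, active_dur = 300) {
  plan <- rbind(
    if (length(passive_days))
      data.frame(entry_min = passive_days * 1440 + 240,
                 duration_min = passive_dur, arousal = "passive"),
    if (length(active_days))
      data.frame(entry_min = active_days * 1440 + 1140,
                 duration_min = active_dur, arousal = "active")
  )
  plan[order(plan$entry_min), , drop = FALSE]
}

# Piecewise mixed data without the scenario layer.
mk_piecewise <- function(n_id = 6, setpoints = c(28, 32, 36, 40, 42, 44),
                         psi = 35, slope_below = 0, slope_above = 2,
                         intercept = 1, rand_sd = 0, resid_sd = 0,
                         ta_jitter = 0, seed = 1) {
  cfg <- suppressWarnings(resp_sim_config(
    n = c(g = n_id), setpoints = setpoints, psi = c(g = psi),
    slope_below = slope_below, slope_above = slope_above,
    intercept = intercept, random_intercept_sd = rand_sd,
    residual_sd = resid_sd, ta_jitter = ta_jitter, response = "y",
    seed = seed))
  gen_respirometry(cfg)
}

# Protocol-derived breakpoint bounds: second-highest setpoint above.
study_bounds <- function(points) {
  sp <- sort(unique(points$ta_set))
  c(sp[1], sp[length(sp) - 1])
}
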