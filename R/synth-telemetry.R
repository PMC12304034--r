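# Synthetic skin-temperature telemetry with known ground truth.
#
# Emulates the field data stream of a temperature-telemetry study: a
# transmitter sampled every ~10 min on a roosting bat, a shaded ambient
# logger every 60 min, optional roost logger, and a plan of torpor bouts
# with active or passive arousals. The generator returns both the trace and
# a ground-truth bout table so detector and classifier can be scored.

#' Configuration for the telemetry generator
#'
#' @param n_days number of full days to simulate.
#' @param ta_min,ta_max daily minimum / maximum ambient temperature (degC)
#'   of the sinusoidal profile; the minimum occurs 30 min before sunrise.
#' @param bout_plan data.frame with columns `entry_min` (minutes from trace
#'   start), `duration_min` (> 0, time below the torpor threshold) and
#'   `arousal` (one of `"active"`, `"passive"`, `"none"`); bouts must not
#'   overlap. `"none"` leaves the bout un-aroused (it is cut by the next
#'   event or the trace end).
#' @param normothermic_tskin degC, resting skin temperature outside torpor.
#' @param torpid_offset degC by which torpid skin temperature sits above
#'   ambient.
#' @param noise_sd degC, white measurement noise added to skin temperature.
#' @param sample_interval min, transmitter sampling interval.
#' @param ta_interval min, ambient logger interval.
#' @param threshold degC, torpor threshold used to anchor arousal timing.
#' @param active_rate degC min^-1, rewarming rate of the active phase.
#' @param sunrise_min,sunset_min minutes after local midnight.
#' @param troost logical, also emit a (damped, lagged) roost-temperature
#'   series.
#' @param seed integer seed.
#' @return object of class `telemetry_sim_config`.
#' @export
telemetry_sim_config <- function(n_days,
                                 ta_min = 12.3, ta_max = 25.0,
                                 bout_plan = NULL,
                                 normothermic_tskin = 35.2,
                                 torpid_offset = 2,
                                 noise_sd = 0,
                                 sample_interval = 10,
                                 ta_interval = 60,
                                 threshold = 28,
                                 active_rate = 1.0,
                                 sunrise_min = 360, sunset_min = 1140,
                                 troost = FALSE,
                                 seed = 1L) {
  if (!is_count(n_days)) stopf("`n_days` must be a positive integer")
  if (sample_interval <= 0 || ta_interval <= 0)
    stopf("sampling intervals must be positive")
  if (ta_max <= ta_min) stopf("`ta_max` must exceed `ta_min`")
  if (is.null(bout_plan))
    bout_plan <- data.frame(entry_min = numeric(), duration_min = numeric(),
                            arousal = character())
  need <- c("entry_min", "duration_min", "arousal")
  if (!all(need %in% names(bout_plan)))
    stopf("`bout_plan` needs columns %s", paste(need, collapse = ", "))
  if (nrow(bout_plan)) {
    if (any(bout_plan$duration_min <= 0)) stopf("bout durations must be > 0")
    if (!all(bout_plan$arousal %in% c("active", "passive", "none")))
      stopf("arousal must be active, passive or none")
    o <- order(bout_plan$entry_min)
    bout_plan <- bout_plan[o, , drop = FALSE]
    ends <- bout_plan$entry_min + bout_plan$duration_min
    if (any(bout_plan$entry_min[-1] < ends[-length(ends)]))
      stopf("bouts overlap")
  }
  structure(list(
    n_days = n_days, ta_min = ta_min, ta_max = ta_max,
    bout_plan = bout_plan, normothermic_tskin = normothermic_tskin,
    torpid_offset = torpid_offset, noise_sd = noise_sd,
    sample_interval = sample_interval, ta_interval = ta_interval,
    threshold = threshold, active_rate = active_rate,
    sunrise_min = sunrise_min, sunset_min = sunset_min,
    troost = troost, seed = as.integer(seed)
  ), class = "telemetry_sim_config")
}

# Continuous sinusoidal ambient temperature (minutes from trace start at
# local midnight); daily minimum 30 min before sunrise.
#' @keywords internal
#' @noRd
ta_sinusoid <- function(t_min, cfg) {
  mid <- (cfg$ta_min + cfg$ta_max) / 2
  amp <- (cfg$ta_max - cfg$ta_min) / 2
  t0 <- cfg$sunrise_min - 30
  mid - amp * cos(2 * pi * (t_min - t0) / 1440)
}

#' Generate a telemetry trace with ground truth
#'
#' Builds a skin-temperature series over `n_days` with the planned torpor
#' bouts. During a bout the skin temperature tracks ambient plus
#' `torpid_offset`; the arousal's final phase is an active rise at
#' `active_rate` timed so the torpor threshold is crossed `duration_min`
#' minutes after entry. Whether a bout reads as "active" or "passive"
#' depends on where the crossing falls relative to the ambient minimum: an
#' arousal completed while ambient is flat or falling shows only the steep
#' endogenous rise, while a late-morning arousal first tracks the ambient
#' rise (partial passive rewarming) before the final jump.
#'
#' @param config a [telemetry_sim_config()].
#' @return list with `trace` (a [telemetry_trace()]) and `truth`, a
#'   data.frame of generated bouts with the configured entry/crossing times,
#'   the configured (continuous) duration, the on-grid duration
#'   (`duration_sampled`, the span of torpid samples the detector can see),
#'   and the planned arousal kind.
#' @export
gen_telemetry <- function(config) {
  stopifnot(inherits(config, "telemetry_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  total <- cfg$n_days * 1440
  t_s <- seq(0, total - cfg$sample_interval, by = cfg$sample_interval)
  ta_true <- ta_sinusoid(t_s, cfg)
  tskin <- rep(cfg$normothermic_tskin, length(t_s))

  plan <- cfg$bout_plan
  truth <- NULL
  for (i in seq_len(nrow(plan))) {
    e <- plan$entry_min[i]
    dur <- plan$duration_min[i]
    kind <- plan$arousal[i]
    cross <- e + dur
    if (kind == "none" || cross > total) {
      idx <- t_s >= e
      tskin[idx] <- ta_true[idx] + cfg$torpid_offset
      kind <- "none"; cross <- NA_real_
    } else {
      # the active rise is the line through (cross, threshold) with slope
      # `active_rate`; the bat follows the torpid track until the line
      # overtakes it, so the threshold is crossed exactly at `cross`
      reach <- cross + (cfg$normothermic_tskin - cfg$threshold) / cfg$active_rate
      idx <- t_s >= e & t_s < reach
      line <- cfg$threshold + cfg$active_rate * (t_s[idx] - cross)
      tskin[idx] <- pmin(cfg$normothermic_tskin,
                         pmax(ta_true[idx] + cfg$torpid_offset, line))
    }
    sub <- t_s >= e & (if (is.na(cross)) TRUE else t_s < cross) &
      tskin < cfg$threshold
    truth <- rbind(truth, data.frame(
      bout = i, entry_min = e, crossing_min = cross,
      duration_min = dur,
      first_sample_min = if (any(sub)) min(t_s[sub]) else NA_real_,
      last_sample_min = if (any(sub)) max(t_s[sub]) else NA_real_,
      duration_sampled = if (any(sub)) max(t_s[sub]) - min(t_s[sub]) else NA_real_,
      arousal = plan$arousal[i],
      censored = is.na(cross)
    ))
  }
  if (cfg$noise_sd > 0) tskin <- tskin + stats::rnorm(length(tskin), 0, cfg$noise_sd)

  t_ta <- seq(0, total - cfg$ta_interval, by = cfg$ta_interval)
  origin <- as.POSIXct("2022-12-01 00:00:00", tz = "UTC")
  troost <- NULL
  if (isTRUE(cfg$troost)) {
    mid <- (cfg$ta_min + cfg$ta_max) / 2 + 2
    amp <- (cfg$ta_max - cfg$ta_min) / 2 * 0.6
    troost <- data.frame(
      time = origin + t_ta * 60,
      troost = mid - amp * cos(2 * pi * (t_ta - (cfg$sunrise_min + 90)) / 1440)
    )
  }
  sun <- data.frame(
    date = as.Date(origin) + seq_len(cfg$n_days) - 1,
    sunrise = origin + ((seq_len(cfg$n_days) - 1) * 1440 + cfg$sunrise_min) * 60,
    sunset = origin + ((seq_len(cfg$n_days) - 1) * 1440 + cfg$sunset_min) * 60
  )
  trace <- telemetry_trace(
    samples = data.frame(time = origin + t_s * 60, tskin = tskin),
    ta = data.frame(time = origin + t_ta * 60, ta = ta_sinusoid(t_ta, cfg)),
    troost = troost, sun = sun,
    id = "sim01", sex = "male", mass_g = 7.6
  )
  if (!is.null(truth)) {
    truth$entry_time <- origin + truth$entry_min * 60
    truth$crossing_time <- origin + ifelse(is.na(truth$crossing_min), NA,
                                           truth$crossing_min) * 60
  } else {
    truth <- data.frame(bout = integer(), entry_min = numeric(),
                        crossing_min = numeric(), duration_min = numeric(),
                        first_sample_min = numeric(), last_sample_min = numeric(),
                        duration_sampled = numeric(), arousal = character(),
                        censored = logical())
  }
  list(trace = trace, truth = truth)
}
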