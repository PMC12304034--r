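# Synthetic raw flow-through respirometry traces.
#
# Inverts the reduction pipeline: given per-setpoint physiological values
# (VCO2, EWL, Tsub), emits the 5-s multichannel analyser trace a stepped
# trial would have produced -- multiplexed baseline and chamber segments,
# first-order chamber washout, optional analyser drift, lag and noise, and
# an optional mid-segment activity bump so the "lowest stable" window is a
# real choice. Reducing the emitted trace must recover the inputs, which
# makes this generator the reduction module's oracle.

#' Construct a respirometry trial
#'
#' @param data data.frame of 5-s samples with columns `time_s`, `source`
#'   (`"baseline"` or `"chamber"`), `frac_co2`, `frac_h2o`,
#'   `flow_ml_min`, `ta_chamber`, `tsub`.
#' @param schedule data.frame with `ta_set`, `start_s`, `end_s`: the clock
#'   window of each setpoint's chamber segment. Setpoints must follow the
#'   stepped protocol order (increasing).
#' @param id,sex metadata; `mass_start_g`, `mass_end_g` masses (g).
#' @param termination list with `ta` (degC) and `reason` (`"behavioural"`
#'   or `"completed"`).
#' @return object of class `resp_trial`.
#' @export
resp_trial <- function(data, schedule, id = NA_character_,
                       sex = NA_character_, mass_start_g = NA_real_,
                       mass_end_g = NA_real_,
                       termination = list(ta = NA_real_, reason = "completed")) {
  need <- c("time_s", "source", "frac_co2", "frac_h2o", "flow_ml_min",
            "ta_chamber", "tsub")
  if (!all(need %in% names(data)))
    stopf("trial data needs columns %s", paste(need, collapse = ", "))
  if (any(data$frac_co2 < 0, na.rm = TRUE) || any(data$frac_h2o < 0, na.rm = TRUE))
    stopf("negative fractional concentrations")
  fl <- data$flow_ml_min
  if (any(fl < 600 | fl > 2600))
    stopf("flow rate outside the supported 600-2600 ml min^-1 range")
  if (is.unsorted(schedule$ta_set, strictly = TRUE))
    stopf("setpoint schedule must be strictly increasing (stepped protocol)")
  structure(list(data = data, schedule = schedule, id = id, sex = sex,
                 mass_start_g = mass_start_g, mass_end_g = mass_end_g,
                 termination = termination, corrected = FALSE,
                 frac_in = NULL, lag_s = NA_real_),
            class = "resp_trial")
}

#' @export
print.resp_trial <- function(x, ...) {
  cat(sprintf("Respirometry trial '%s' (%s): %d samples, %d setpoints (%s degC)\n",
              x$id, x$sex, nrow(x$data), nrow(x$schedule),
              paste(x$schedule$ta_set, collapse = ", ")))
  cat(sprintf("  terminated at %s degC (%s); drift/lag corrected: %s\n",
              format(x$termination$ta), x$termination$reason,
              if (x$corrected) "yes" else "no"))
  invisible(x)
}

#' Emit a raw gas trace for known physiological values
#'
#' @param physio data.frame with one row per setpoint: `ta_set` (degC,
#'   increasing), `vco2` (ml min^-1), `ewl_g_h` (g h^-1), `tsub` (degC).
#' @param flow_ml_min chamber flow rate (must lie in 600--2600).
#' @param drift_rate analyser drift in fractional units per hour, applied
#'   linearly to both channels and both lines.
#' @param lag_s analyser lag (s): the recorded fraction channels are the
#'   true signal delayed by this much.
#' @param noise_sd fractional-concentration noise SD (absolute units).
#' @param frac_in_co2,frac_in_h2o incurrent (baseline) fractions; dried air
#'   retains some CO2 but essentially no water.
#' @param baseline_min,chamber_min minutes of baseline / chamber recording
#'   per setpoint; a closing baseline is appended so chamber segments are
#'   bracketed.
#' @param washout_tau_s chamber washout time constant (s) of the
#'   first-order approach to steady state after each step.
#' @param bump relative height of a transient activity bump in the middle
#'   of each chamber segment (0 disables); the stable-window search must
#'   avoid it.
#' @param tsub_noise_sd degC noise on the subcutaneous channel.
#' @param interval_s sampling interval (default 5 s).
#' @inheritParams resp_trial
#' @param seed integer seed for the noise draws.
#' @return a [resp_trial()].
#' @export
gen_raw_gas_trace <- function(physio, flow_ml_min = 1000,
                              drift_rate = 0, lag_s = 0, noise_sd = 0,
                              frac_in_co2 = 4e-4, frac_in_h2o = 0,
                              baseline_min = 3, chamber_min = 28,
                              washout_tau_s = 45, bump = 0,
                              tsub_noise_sd = 0, interval_s = 5,
                              id = "sim01", sex = NA_character_,
                              mass_start_g = 8, mass_end_g = NA_real_,
                              termination = NULL, seed = 1L) {
  need <- c("ta_set", "vco2", "ewl_g_h", "tsub")
  if (!all(need %in% names(physio)))
    stopf("`physio` needs columns %s", paste(need, collapse = ", "))
  if (flow_ml_min < 600 || flow_ml_min > 2600)
    stopf("flow rate %.0f outside 600-2600 ml min^-1", flow_ml_min)
  if (any(physio$vco2 < 0) || any(physio$ewl_g_h < 0))
    stopf("physiological rates must be non-negative")
  set.seed(as.integer(seed))
  vap <- energy_constants()$vapour_density
  b_s <- baseline_min * 60; c_s <- chamber_min * 60
  n_sp <- nrow(physio)
  total_s <- n_sp * (b_s + c_s) + b_s
  t <- seq(0, total_s - interval_s, by = interval_s)

  source <- rep("baseline", length(t))
  fe_co2 <- rep(frac_in_co2, length(t))
  fe_h2o <- rep(frac_in_h2o, length(t))
  ta_ch <- rep(physio$ta_set[1], length(t))
  tsub <- rep(physio$tsub[1], length(t))
  schedule <- data.frame(ta_set = physio$ta_set,
                         start_s = NA_real_, end_s = NA_real_)
  for (k in seq_len(n_sp)) {
    s0 <- (k - 1) * (b_s + c_s) + b_s
    s1 <- s0 + c_s
    schedule$start_s[k] <- s0; schedule$end_s[k] <- s1
    ch <- t >= s0 & t < s1
    source[ch] <- "chamber"
    # steady-state excess fractions implied by the mass balance
    d_co2 <- physio$vco2[k] / flow_ml_min
    d_h2o <- (physio$ewl_g_h[k] * 1000 / 60) / vap / flow_ml_min
    wash <- 1 - exp(-(t[ch] - s0) / washout_tau_s)
    fe_co2[ch] <- frac_in_co2 + d_co2 * wash
    fe_h2o[ch] <- frac_in_h2o + d_h2o * wash
    if (bump > 0) {
      mid <- (s0 + s1) / 2
      bmp <- exp(-((t[ch] - mid) / 120)^2)
      fe_co2[ch] <- fe_co2[ch] + bump * d_co2 * bmp
      fe_h2o[ch] <- fe_h2o[ch] + bump * d_h2o * bmp
    }
    seg <- t >= s0 - b_s & t < s1
    ta_ch[seg] <- physio$ta_set[k]
    tsub[seg] <- physio$tsub[k]
    if (k == n_sp) { ta_ch[t >= s1] <- physio$ta_set[k]; tsub[t >= s1] <- physio$tsub[k] }
  }
  # analyser lag: the recorded signal is the true signal `lag_s` ago
  if (lag_s > 0) {
    shift <- round(lag_s / interval_s)
    if (shift > 0) {
      fe_co2 <- c(rep(fe_co2[1], shift), fe_co2[seq_len(length(t) - shift)])
      fe_h2o <- c(rep(fe_h2o[1], shift), fe_h2o[seq_len(length(t) - shift)])
    }
  }
  if (drift_rate != 0) {
    d <- drift_rate * t / 3600
    fe_co2 <- fe_co2 + d
    fe_h2o <- fe_h2o + d
  }
  if (noise_sd > 0) {
    fe_co2 <- pmax(0, fe_co2 + stats::rnorm(length(t), 0, noise_sd))
    fe_h2o <- pmax(0, fe_h2o + stats::rnorm(length(t), 0, noise_sd))
  }
  if (tsub_noise_sd > 0) tsub <- tsub + stats::rnorm(length(t), 0, tsub_noise_sd)

  if (is.null(termination))
    termination <- list(ta = physio$ta_set[n_sp], reason = "completed")
  resp_trial(
    data = data.frame(time_s = t, source = source, frac_co2 = fe_co2,
                      frac_h2o = fe_h2o, flow_ml_min = flow_ml_min,
                      ta_chamber = ta_ch, tsub = tsub),
    schedule = schedule, id = id, sex = sex,
    mass_start_g = mass_start_g, mass_end_g = mass_end_g,
    termination = termination
  )
}
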