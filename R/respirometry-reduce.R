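# Reduction of raw respirometry trials to per-setpoint physiology.

#' Estimate analyser lag from segment transitions
#'
#' The multiplexer switch between baseline and chamber lines produces steps
#' in the fraction channels; tubing and analyser response delay them. The
#' lag is estimated as the backward shift of the channels that minimises
#' the within-segment variance of the CO2 channel across the known switch
#' schedule (a discrete cross-correlation of the step pattern).
#'
#' @param trial a [resp_trial()].
#' @param max_lag_s largest lag considered (s).
#' @return estimated lag in seconds (a multiple of the sampling interval).
#' @export
estimate_lag <- function(trial, max_lag_s = 60) {
  stopifnot(inherits(trial, "resp_trial"))
  d <- trial$data
  dt <- stats::median(diff(d$time_s))
  shifts <- seq(0, max_lag_s, by = dt)
  seg_id <- cumsum(c(1L, d$source[-1] != d$source[-nrow(d)]))
  score <- vapply(shifts, function(L) {
    k <- round(L / dt)
    x <- if (k > 0) c(d$frac_co2[-seq_len(k)], rep(NA, k)) else d$frac_co2
    sum(tapply(x, seg_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::var(v) * (length(v) - 1) else 0
    }))
  }, numeric(1))
  shifts[which.min(score)]
}

#' Correct analyser drift and lag
#'
#' Removes the constant analyser lag by shifting the fraction channels back
#' in time, then removes linear drift: per channel, baseline-segment means
#' are computed at their segment mid-times, the drift at any time is
#' interpolated linearly between consecutive baseline means, and the
#' deviation from the first baseline's mean is subtracted. The first
#' baseline's mean is retained as the incurrent fraction for the mass
#' balance. With a single (non-bracketing) baseline segment a constant
#' baseline subtraction is used instead, with a warning.
#'
#' @param trial a [resp_trial()].
#' @param lag_s analyser lag in seconds, or `NULL` to estimate it with
#'   [estimate_lag()].
#' @return the corrected `resp_trial` (`corrected = TRUE`), with the
#'   incurrent fractions in `$frac_in` and the applied lag in `$lag_s`.
#' @export
correct_drift_lag <- function(trial, lag_s = NULL) {
  stopifnot(inherits(trial, "resp_trial"))
  d <- trial$data
  dt <- stats::median(diff(d$time_s))
  if (is.null(lag_s)) lag_s <- estimate_lag(trial)
  k <- round(lag_s / dt)
  if (k > 0) {
    for (ch in c("frac_co2", "frac_h2o"))
      d[[ch]] <- c(d[[ch]][-seq_len(k)], rep(d[[ch]][nrow(d)], k))
  }
  seg_id <- cumsum(c(1L, d$source[-1] != d$source[-nrow(d)]))
  base_segs <- unique(seg_id[d$source == "baseline"])
  if (length(base_segs) < 1)
    stopf("trial has no baseline segments")
  frac_in <- c(co2 = NA_real_, h2o = NA_real_)
  for (ch in c("frac_co2", "frac_h2o")) {
    mids <- vapply(base_segs, function(s) mean(d$time_s[seg_id == s]), numeric(1))
    means <- vapply(base_segs, function(s) mean(d[[ch]][seg_id == s]), numeric(1))
    if (length(base_segs) >= 2 &&
        min(mids) <= min(d$time_s[d$source == "chamber"]) &&
        max(mids) >= max(d$time_s[d$source == "chamber"]) - 0) {
      drift <- stats::approx(mids, means, xout = d$time_s, rule = 2)$y - means[1]
    } else {
      warnf("chamber segments not bracketed by baselines; using single-baseline subtraction")
      drift <- 0
    }
    d[[ch]] <- d[[ch]] - drift
    frac_in[if (ch == "frac_co2") "co2" else "h2o"] <- means[1]
  }
  trial$data <- d
  trial$corrected <- TRUE
  trial$frac_in <- frac_in
  trial$lag_s <- lag_s
  trial
}

#' Select the lowest stable window of a channel
#'
#' Slides a window of `width_s` over the series and, among windows whose
#' within-window linear slope and coefficient of variation are small enough
#' to count as stable, returns the one with the lowest mean (the resting
#' reading). If no window qualifies, the lowest-CV window is returned and
#' flagged unstable.
#'
#' @param time_s,values numeric vectors (regular sampling).
#' @param width_s window width in seconds (default 300, i.e. 5 min).
#' @param slope_frac_per_min stability bound on |slope| as a fraction of
#'   the window mean per minute (default 0.02).
#' @param cv_max stability bound on the coefficient of variation (default
#'   0.05).
#' @return list with `start_s`, `end_s`, `mean`, `sd`, `cv`,
#'   `slope_per_min`, `stable`, `idx` (sample index range).
#' @export
select_stable_window <- function(time_s, values, width_s = 300,
                                 slope_frac_per_min = 0.02, cv_max = 0.05) {
  n <- length(values)
  if (n != length(time_s)) stopf("time and value lengths differ")
  dt <- stats::median(diff(time_s))
  w <- round(width_s / dt)
  if (w < 2 || n < w) stopf("segment shorter than the %g-s window", width_s)
  # running mean / variance / slope via cumulative sums
  cs <- cumsum(values); cs2 <- cumsum(values^2)
  x <- seq_len(w) - (w + 1) / 2          # centred sample index within window
  sxx <- sum(x^2)
  n_win <- n - w + 1
  means <- (cs[w:n] - c(0, cs[seq_len(n_win - 1)])) / w
  ss <- (cs2[w:n] - c(0, cs2[seq_len(n_win - 1)])) - w * means^2
  sds <- sqrt(pmax(ss, 0) / (w - 1))
  sxy <- vapply(seq_len(n_win), function(i)
    sum(x * values[i:(i + w - 1)]), numeric(1))
  slope <- (sxy / sxx) / dt * 60         # units per minute
  cv <- ifelse(means != 0, sds / abs(means), Inf)
  stable <- abs(slope) <= slope_frac_per_min * pmax(abs(means), .Machine$double.eps) &
    cv <= cv_max
  pick <- if (any(stable)) which(stable)[which.min(means[stable])] else which.min(cv)
  i0 <- pick; i1 <- pick + w - 1
  list(start_s = time_s[i0], end_s = time_s[i1], mean = means[pick],
       sd = sds[pick], cv = cv[pick], slope_per_min = slope[pick],
       stable = any(stable), idx = c(i0, i1))
}

#' Reduce a trial to per-setpoint physiological points
#'
#' For each setpoint reached before termination: drops the equilibration
#' prefix of the chamber segment, selects the lowest stable 5-min window of
#' the CO2 and water-vapour channels (independently by default), applies
#' the mass-balance equations with the baseline-derived incurrent
#' fractions, and converts to whole-animal metabolic rate, evaporative
#' water loss, evaporative heat loss and EHL/MHP. Subcutaneous temperature
#' is averaged over the CO2 window. Uncorrected trials are corrected first
#' with default settings.
#'
#' @param trial a [resp_trial()].
#' @param constants an [energy_constants()] bundle.
#' @param equil_min minutes of each chamber segment excluded as
#'   equilibration (default 20).
#' @param width_min stable-window width in minutes (default 5).
#' @param shared_window logical; force the H2O rate to be read over the CO2
#'   window instead of its own lowest stable window.
#' @param mass one of `"start"` (default: the trial's starting mass is
#'   assigned to every point) or `"interpolate"` (linear in time between
#'   start and end mass).
#' @inheritParams select_stable_window
#' @return data.frame of class `physio_points`: one row per setpoint with
#'   `id`, `sex`, `mass_g`, `ta_set`, `tsub`, `vco2` (ml min^-1), `warmr_w`,
#'   `waewl_g_h`, `ehl_w`, `ehl_mhp`, window clocks and stability flags.
#' @export
reduce_trial <- function(trial, constants = energy_constants(),
                         equil_min = 20, width_min = 5,
                         shared_window = FALSE,
                         slope_frac_per_min = 0.02, cv_max = 0.05,
                         mass = c("start", "interpolate")) {
  stopifnot(inherits(trial, "resp_trial"))
  mass <- match.arg(mass)
  if (!trial$corrected) trial <- correct_drift_lag(trial)
  d <- trial$data
  out <- list()
  for (k in seq_len(nrow(trial$schedule))) {
    s0 <- trial$schedule$start_s[k]; s1 <- trial$schedule$end_s[k]
    ch <- which(d$source == "chamber" & d$time_s >= s0 + equil_min * 60 &
                  d$time_s < s1)
    if (length(ch) < 2) {
      warnf("setpoint %.0f: no usable chamber data after equilibration; skipped",
            trial$schedule$ta_set[k])
      next
    }
    win_co2 <- select_stable_window(d$time_s[ch], d$frac_co2[ch],
                                    width_s = width_min * 60,
                                    slope_frac_per_min = slope_frac_per_min,
                                    cv_max = cv_max)
    win_h2o <- if (shared_window) win_co2 else
      select_stable_window(d$time_s[ch], d$frac_h2o[ch],
                           width_s = width_min * 60,
                           slope_frac_per_min = slope_frac_per_min,
                           cv_max = cv_max)
    flow <- mean(d$flow_ml_min[ch])
    vco2 <- compute_vco2(flow, win_co2$mean, flow, trial$frac_in["co2"])
    ewl_g_h <- compute_ewl(flow, win_h2o$mean, flow, trial$frac_in["h2o"],
                           constants = constants, units = "g_h")
    vco2 <- max(vco2, 0); ewl_g_h <- max(ewl_g_h, 0)
    warmr <- vco2_to_watts(vco2, constants)
    er <- ehl_and_ratio(ewl_g_h, warmr, constants)
    co2_idx <- ch[win_co2$idx[1]:win_co2$idx[2]]
    m <- if (mass == "start" || is.na(trial$mass_end_g)) trial$mass_start_g else {
      frac_t <- mean(d$time_s[co2_idx]) / max(d$time_s)
      trial$mass_start_g + frac_t * (trial$mass_end_g - trial$mass_start_g)
    }
    out[[length(out) + 1]] <- data.frame(
      id = trial$id, sex = trial$sex, mass_g = m,
      ta_set = trial$schedule$ta_set[k],
      tsub = mean(d$tsub[co2_idx]),
      vco2 = unname(vco2), warmr_w = unname(warmr),
      waewl_g_h = unname(ewl_g_h),
      ehl_w = er$ehl_w, ehl_mhp = er$ehl_mhp,
      co2_win_start_s = win_co2$start_s, co2_win_end_s = win_co2$end_s,
      h2o_win_start_s = win_h2o$start_s, h2o_win_end_s = win_h2o$end_s,
      co2_stable = win_co2$stable, h2o_stable = win_h2o$stable
    )
  }
  if (!length(out)) stopf("no reducible setpoints in trial")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("physio_points", "data.frame")
  res
}
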