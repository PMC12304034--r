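# Torpor-bout detection and summary from skin-temperature telemetry.

#' Construct a telemetry trace
#'
#' Container for one individual's telemetry deployment: skin temperature at
#' a nominal 10-min interval, shaded ambient temperature at a nominal 60-min
#' interval, optionally roost temperature and per-day sunrise/sunset times.
#'
#' @param samples data.frame with `time` (POSIXct, strictly increasing) and
#'   `tskin` (degC).
#' @param ta optional data.frame with `time` and `ta` (degC).
#' @param troost optional data.frame with `time` and `troost` (degC).
#' @param sun optional data.frame with `date`, `sunrise`, `sunset`.
#' @param id,sex character metadata; `mass_g` numeric.
#' @return object of class `telemetry_trace`.
#' @export
telemetry_trace <- function(samples, ta = NULL, troost = NULL, sun = NULL,
                            id = NA_character_, sex = NA_character_,
                            mass_g = NA_real_) {
  if (!is.data.frame(samples) || !all(c("time", "tskin") %in% names(samples)))
    stopf("`samples` must have columns time and tskin")
  if (nrow(samples) == 0) stopf("empty trace")
  chk_times <- function(x, what) {
    if (!inherits(x, "POSIXct")) stopf("%s times must be POSIXct", what)
    if (is.unsorted(as.numeric(x), strictly = TRUE))
      stopf("%s timestamps must be strictly increasing", what)
  }
  chk_times(samples$time, "sample")
  if (!is.null(ta)) chk_times(ta$time, "ta")
  if (!is.null(troost)) chk_times(troost$time, "troost")
  structure(list(samples = samples, ta = ta, troost = troost, sun = sun,
                 id = id, sex = sex, mass_g = mass_g),
            class = "telemetry_trace")
}

#' @export
print.telemetry_trace <- function(x, ...) {
  span <- diff(range(as.numeric(x$samples$time))) / 86400
  cat(sprintf("Telemetry trace '%s' (%s): %d Tskin samples over %.1f days\n",
              x$id, x$sex, nrow(x$samples), span))
  if (!is.null(x$ta)) cat(sprintf("  ambient series: %d samples\n", nrow(x$ta)))
  if (!is.null(x$troost)) cat(sprintf("  roost series: %d samples\n", nrow(x$troost)))
  invisible(x)
}

#' @keywords internal
#' @noRd
interp_ta <- function(ta, at) {
  if (is.null(ta) || nrow(ta) < 2) return(rep(NA_real_, length(at)))
  stats::approx(as.numeric(ta$time), ta$ta, xout = as.numeric(at), rule = 2)$y
}

#' Detect torpor bouts
#'
#' A torpor bout is a maximal run of skin-temperature samples strictly below
#' `threshold` whose time span strictly exceeds `min_duration` (the
#' conventional "below 28 degC for more than 30 min" rule). Runs are split
#' at recording gaps longer than `max_gap` -- the record cannot certify the
#' animal stayed torpid across the gap -- and both fragments, as well as
#' runs touching either end of the trace, are marked censored.
#'
#' @param trace a [telemetry_trace()].
#' @param threshold degC; comparison is strict (`tskin < threshold`).
#' @param min_duration min; span must strictly exceed this.
#' @param max_gap min; sampling gaps longer than this split a run.
#' @return data.frame of class `torpor_bouts`: one row per bout with
#'   `start`, `end` (times of the first/last sub-threshold samples),
#'   `duration_min` (`end - start`), `ta_at_entry` (ambient interpolated at
#'   bout start; `NA` without an ambient series), `min_tskin`, `censored`,
#'   `entry_phase` (`pre-dawn` within 120 min before sunrise, else `day`,
#'   `night`, or `unknown` without sun times) and `arousal`
#'   (`"unclassified"`; see [classify_arousal()]).
#' @examples
#' tr <- gen_telemetry(telemetry_sim_config(
#'   2, bout_plan = data.frame(entry_min = 240, duration_min = 300,
#'                             arousal = "passive")))
#' detect_torpor_bouts(tr$trace)
#' @export
detect_torpor_bouts <- function(trace, threshold = 28, min_duration = 30,
                                max_gap = 30) {
  stopifnot(inherits(trace, "telemetry_trace"))
  s <- trace$samples
  if (nrow(s) < 2) stopf("need at least 2 samples to detect bouts")
  tn <- as.numeric(s$time) / 60   # minutes
  below <- !is.na(s$tskin) & s$tskin < threshold

  # maximal runs of below-threshold samples, split at long gaps
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    gap_after <- which(diff(tn[idx]) > max_gap)
    segs <- split(idx, cumsum(c(0, seq_along(idx[-1]) %in% gap_after)))
    n_segs <- length(segs)
    for (j in seq_len(n_segs)) {
      seg <- segs[[j]]
      gap_censored <- n_segs > 1 && (j < n_segs || j > 1)
      edge_censored <- seg[1] == 1 || seg[length(seg)] == nrow(s)
      rows[[length(rows) + 1]] <- data.frame(
        i_start = seg[1], i_end = seg[length(seg)],
        censored = gap_censored || edge_censored
      )
    }
  }
  if (!length(rows)) return(empty_bouts())
  b <- do.call(rbind, rows)
  b$start <- s$time[b$i_start]
  b$end <- s$time[b$i_end]
  b$duration_min <- tn[b$i_end] - tn[b$i_start]
  b <- b[b$duration_min > min_duration, , drop = FALSE]
  if (!nrow(b)) return(empty_bouts())
  b$ta_at_entry <- interp_ta(trace$ta, b$start)
  b$min_tskin <- vapply(seq_len(nrow(b)),
                        function(i) min(s$tskin[b$i_start[i]:b$i_end[i]]),
                        numeric(1))
  b$entry_phase <- entry_phase(b$start, trace$sun)
  b$arousal <- "unclassified"
  rownames(b) <- NULL
  class(b) <- c("torpor_bouts", "data.frame")
  b
}

#' @keywords internal
#' @noRd
empty_bouts <- function() {
  b <- data.frame(i_start = integer(), i_end = integer(), censored = logical(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric(), ta_at_entry = numeric(),
                  min_tskin = numeric(), entry_phase = character(),
                  arousal = character())
  class(b) <- c("torpor_bouts", "data.frame")
  b
}

# Entry phase: pre-dawn = within `window` minutes before that day's sunrise.
#' @keywords internal
#' @noRd
entry_phase <- function(start, sun, window = 120) {
  if (is.null(sun)) return(rep("unknown", length(start)))
  out <- character(length(start))
  for (i in seq_along(start)) {
    d <- as.Date(start[i])
    row <- sun[sun$date == d, , drop = FALSE]
    if (!nrow(row)) { out[i] <- "unknown"; next }
    dt_sr <- as.numeric(difftime(row$sunrise[1], start[i], units = "mins"))
    out[i] <- if (dt_sr > 0 && dt_sr <= window) "pre-dawn"
      else if (start[i] >= row$sunrise[1] && start[i] <= row$sunset[1]) "day"
      else "night"
  }
  out
}

#' Classify arousals as active or passive
#'
#' Examines the rewarming segment of each non-censored bout, from the bout's
#' skin-temperature minimum to the first sample at or above the torpor
#' threshold. An arousal is labelled passive when an initial sub-segment of
#' at least 3 samples rewarms slowly (mean rate at most `r_passive`) while
#' tracking ambient temperature (|dTskin/dt - dTa/dt| at most `ta_match`),
#' i.e. partial passive rewarming precedes the final active rise; otherwise
#' it is active. Segments with fewer than 3 samples, bouts without an
#' ambient series, and censored bouts stay `"unclassified"`.
#'
#' @param bouts a `torpor_bouts` data.frame from [detect_torpor_bouts()].
#' @param trace the [telemetry_trace()] the bouts came from.
#' @param threshold degC, torpor threshold used for the crossing sample.
#' @param r_passive degC min^-1, maximum rewarming rate of a passive phase.
#' @param ta_match degC min^-1, maximum |dTskin/dt - dTa/dt| for "tracking".
#' @return `bouts` with the `arousal` column filled in.
#' @export
classify_arousal <- function(bouts, trace, threshold = 28,
                             r_passive = 0.3, ta_match = 0.15) {
  stopifnot(inherits(bouts, "torpor_bouts"), inherits(trace, "telemetry_trace"))
  if (!nrow(bouts)) return(bouts)
  s <- trace$samples
  tn <- as.numeric(s$time) / 60
  for (i in seq_len(nrow(bouts))) {
    if (bouts$censored[i]) next
    idx <- bouts$i_start[i]:bouts$i_end[i]
    # rewarming starts at the LAST attainment of the bout minimum; flat
    # torpid stretches before it are maintenance, not arousal
    i_min <- idx[max(which(s$tskin[idx] == min(s$tskin[idx])))]
    i_cross <- bouts$i_end[i] + 1L       # first sample at/above threshold
    if (i_cross > nrow(s)) next
    seg <- i_min:i_cross
    if (length(seg) < 3) {
      # steep arousals can jump within one sampling interval; pad the
      # segment backward into the bout so the Ta-dependence of the initial
      # steps can still be assessed
      seg <- max(bouts$i_start[i], i_cross - 2L):i_cross
    }
    if (length(seg) < 3) { bouts$arousal[i] <- "unclassified"; next }
    dt <- diff(tn[seg])
    r_skin <- diff(s$tskin[seg]) / dt
    ta_seg <- interp_ta(trace$ta, s$time[seg])
    if (anyNA(ta_seg)) { bouts$arousal[i] <- "unclassified"; next }
    r_ta <- diff(ta_seg) / dt
    slow <- r_skin <= r_passive
    n_pre <- if (!slow[1]) 0L else which.min(c(slow, FALSE)) - 1L
    passive <- n_pre >= 2 && !anyNA(r_ta[seq_len(n_pre)]) &&
      mean(abs(r_skin[seq_len(n_pre)] - r_ta[seq_len(n_pre)])) <= ta_match
    bouts$arousal[i] <- if (passive) "passive" else "active"
  }
  bouts
}

#' Daily temperature summaries
#'
#' Per-day minima, maxima and ranges of skin, ambient and roost temperature
#' (day boundary at local midnight), and a pooled summary: mean and SD of
#' the daily minima and maxima, absolute extremes, and the mean daily range.
#' Days with fewer than half the expected skin-temperature samples are
#' excluded with a message.
#'
#' @param trace a [telemetry_trace()].
#' @param min_coverage minimum fraction of expected samples for a day to
#'   count.
#' @return list with `per_day` (one row per kept day and variable) and
#'   `pooled` (one row per variable: `mean_daily_min`, `sd_daily_min`,
#'   `mean_daily_max`, `sd_daily_max`, `abs_min`, `abs_max`,
#'   `mean_daily_range`, `sd_daily_range`, `n_days`).
#' @export
daily_summaries <- function(trace, min_coverage = 0.5) {
  stopifnot(inherits(trace, "telemetry_trace"))
  series <- list(tskin = trace$samples)
  names(series[[1]])[2] <- "value"
  if (!is.null(trace$ta)) {
    ta <- trace$ta; names(ta)[2] <- "value"; series$ta <- ta
  }
  if (!is.null(trace$troost)) {
    tr <- trace$troost; names(tr)[2] <- "value"; series$troost <- tr
  }
  per_day <- NULL
  for (v in names(series)) {
    df <- series[[v]]
    df$date <- as.Date(df$time)
    spacing <- stats::median(diff(as.numeric(df$time))) / 60
    expected <- 1440 / spacing
    sp <- split(df, df$date)
    keep <- vapply(sp, function(d) nrow(d) >= min_coverage * expected, logical(1))
    if (any(!keep))
      message(sprintf("%s: excluding %d day(s) with < %.0f%% coverage",
                      v, sum(!keep), 100 * min_coverage))
    sp <- sp[keep]
    if (!length(sp)) next
    per_day <- rbind(per_day, data.frame(
      variable = v,
      date = as.Date(names(sp)),
      min = vapply(sp, function(d) min(d$value), numeric(1)),
      max = vapply(sp, function(d) max(d$value), numeric(1)),
      n = vapply(sp, nrow, integer(1)),
      row.names = NULL
    ))
  }
  if (is.null(per_day)) stopf("no day has sufficient coverage")
  per_day$range <- per_day$max - per_day$min
  pooled <- do.call(rbind, lapply(split(per_day, per_day$variable), function(d) {
    data.frame(variable = d$variable[1],
               mean_daily_min = mean(d$min), sd_daily_min = sample_sd(d$min),
               mean_daily_max = mean(d$max), sd_daily_max = sample_sd(d$max),
               abs_min = min(d$min), abs_max = max(d$max),
               mean_daily_range = mean(d$range),
               sd_daily_range = sample_sd(d$range),
               n_days = nrow(d), row.names = NULL)
  }))
  rownames(pooled) <- NULL
  list(per_day = per_day, pooled = pooled)
}

#' Summary statistics over detected bouts
#'
#' Counts bouts, summarises durations over non-censored bouts (censored
#' bouts are counted but excluded from duration statistics), summarises
#' ambient temperature at entry, tabulates bouts per day (by entry date)
#' and entry phases.
#'
#' @param bouts a `torpor_bouts` data.frame.
#' @return list with `n_bouts`, `n_censored`, `duration_mean`,
#'   `duration_sd`, `duration_longest` (all min; `NA` if no complete bout),
#'   `entry_ta_mean`, `entry_ta_sd`, `bouts_per_day` (table of days by bout
#'   multiplicity) and `entry_phase` (counts).
#' @export
bout_statistics <- function(bouts) {
  stopifnot(inherits(bouts, "torpor_bouts"))
  if (!nrow(bouts)) stopf("no bouts to summarise")
  complete <- bouts[!bouts$censored, , drop = FALSE]
  dur <- complete$duration_min
  per_day <- table(as.Date(bouts$start))
  list(
    n_bouts = nrow(bouts),
    n_censored = sum(bouts$censored),
    duration_mean = if (length(dur)) mean(dur) else NA_real_,
    duration_sd = if (length(dur) > 1) sample_sd(dur) else NA_real_,
    duration_longest = if (length(dur)) max(dur) else NA_real_,
    entry_ta_mean = if (any(is.finite(bouts$ta_at_entry)))
      mean(bouts$ta_at_entry, na.rm = TRUE) else NA_real_,
    entry_ta_sd = if (sum(is.finite(bouts$ta_at_entry)) > 1)
      sample_sd(bouts$ta_at_entry[is.finite(bouts$ta_at_entry)]) else NA_real_,
    bouts_per_day = table(factor(as.integer(per_day))),
    entry_phase = table(bouts$entry_phase)
  )
}

#' Read / write telemetry CSV
#'
#' Telemetry CSVs carry ISO-8601 timestamps and a `tskin` column; ambient
#' and roost series are separate two-column CSVs.
#'
#' @param path CSV with columns `time`, `tskin`.
#' @param ta_path,troost_path optional CSVs with `time` and `ta` / `troost`.
#' @param tz timezone of the timestamps.
#' @inheritParams telemetry_trace
#' @return a [telemetry_trace()].
#' @export
read_telemetry_csv <- function(path, ta_path = NULL, troost_path = NULL,
                               tz = "UTC", id = NA_character_,
                               sex = NA_character_, mass_g = NA_real_) {
  rd <- function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    d$time <- as.POSIXct(d$time, tz = tz,
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%d"))
    d
  }
  telemetry_trace(rd(path),
                  ta = if (!is.null(ta_path)) rd(ta_path),
                  troost = if (!is.null(troost_path)) rd(troost_path),
                  id = id, sex = sex, mass_g = mass_g)
}

#' @rdname read_telemetry_csv
#' @param trace a [telemetry_trace()] to write.
#' @export
write_telemetry_csv <- function(trace, path) {
  stopifnot(inherits(trace, "telemetry_trace"))
  out <- trace$samples
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
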