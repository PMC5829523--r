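#' Driving-time features
#'
#' Time in motion versus time stationary for a log or segment slice: total
#' duration, seconds in motion (one nominal sample period per moving sample),
#' the motion/stationary ratio and the percentage of time in motion. The two
#' are consistent: `percent = 100 * ratio / (1 + ratio)` whenever the ratio
#' is finite. A log that never stops has an infinite ratio, flagged.
#'
#' @param samples data.frame with `t`, `speed`, `turn` columns, or a
#'   [joystick_log] (its samples are used).
#' @param deadband motion deadband, counts.
#' @param sample_rate_hz sample rate, Hz (taken from the log if one is given).
#' @return A list of class `timing_features`: `total_s`, `moving_s`, `ratio`,
#'   `percent_moving`, `always_moving` flag.
#' @export
timing <- function(samples, deadband = 2, sample_rate_hz = 50) {
  if (inherits(samples, "joystick_log")) {
    sample_rate_hz <- samples$sample_rate_hz
    samples <- samples$samples
  }
  if (nrow(samples) == 0L) stop("empty input")
  moving <- pmax(abs(samples$speed), abs(samples$turn)) > deadband
  total_s <- nrow(samples) / sample_rate_hz
  moving_s <- sum(moving) / sample_rate_hz
  stationary_s <- total_s - moving_s
  always <- stationary_s == 0
  structure(list(
    total_s = total_s,
    moving_s = moving_s,
    ratio = if (always) Inf else moving_s / stationary_s,
    percent_moving = 100 * moving_s / total_s,
    always_moving = always
  ), class = "timing_features")
}

#' @export
print.timing_features <- function(x, ...) {
  cat(sprintf("<timing_features> %.1f s total, %.1f s moving (%.1f%%), ratio %s\n",
              x$total_s, x$moving_s, x$percent_moving,
              if (x$always_moving) "Inf (never stationary)" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Daily driving aggregates
#'
#' Two summaries per day of logged driving: a segment-wise summary
#' (minimum / median / maximum duration over the sustained motion segments of
#' at least `min_duration_s`) and whole-day pooled values. "Hours in chair"
#' is the span from the first to the last sample of the day's log; "hours
#' driving" the summed moving time over *all* motion, including bouts shorter
#' than the segment threshold.
#'
#' @param logs list of [joystick_log]s, one per day; day labels are taken
#'   from each log's `meta$day` when present, else the list position.
#' @param deadband motion deadband, counts.
#' @param min_duration_s segment threshold, seconds.
#' @return A data.frame with one row per day: `day`, `hours_in_chair`,
#'   `hours_driving`, `ratio`, `percent_moving`, `n_segments`, `seg_min_s`,
#'   `seg_med_s`, `seg_max_s`.
#' @export
daily_aggregate <- function(logs, deadband = 2, min_duration_s = 30) {
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    day <- if (!is.null(log$meta$day)) log$meta$day else i
    s <- log$samples
    tm <- timing(log, deadband)
    seg <- extract_segments(log, min_duration_s, deadband)
    data.frame(
      day = day,
      hours_in_chair = (s$t[nrow(s)] - s$t[1]) / 3.6e6,
      hours_driving = tm$moving_s / 3600,
      ratio = tm$ratio,
      percent_moving = tm$percent_moving,
      n_segments = nrow(seg),
      seg_min_s = if (nrow(seg)) min(seg$duration_s) else NA_real_,
      seg_med_s = if (nrow(seg)) stats::median(seg$duration_s) else NA_real_,
      seg_max_s = if (nrow(seg)) max(seg$duration_s) else NA_real_
    )
  })
  do.call(rbind, rows)
}
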