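#' Flag samples where the platform is in motion
#'
#' A sample counts as moving when the larger joystick axis deflection exceeds
#' the deadband: `max(|speed|, |turn|) > deadband`. The default deadband of
#' 2 counts suppresses quantisation jitter around neutral.
#'
#' @param log a [joystick_log].
#' @param deadband non-negative joystick deflection threshold, counts.
#' @return Logical vector, one entry per sample.
#' @export
detect_motion <- function(log, deadband = 2) {
  stopifnot(deadband >= 0)
  s <- log$samples
  pmax(abs(s$speed), abs(s$turn)) > deadband
}

#' Extract sustained motion segments
#'
#' Maximal contiguous runs of moving samples, after bridging pauses shorter
#' than `merge_tol_s` (brief hesitations inside a driving bout do not split
#' it), keeping only runs of at least `min_duration_s`. Durations count one
#' nominal sample period per sample, so a run of n samples at rate r lasts
#' n/r seconds.
#'
#' @param log a [joystick_log].
#' @param min_duration_s minimum segment duration, seconds.
#' @param deadband motion deadband, counts (see [detect_motion()]).
#' @param merge_tol_s pauses shorter than this do not split a segment, seconds.
#' @return A data.frame with one row per segment: `start_t`, `end_t`
#'   (milliseconds), `start_idx`, `end_idx` (sample rows) and `duration_s`.
#'   May have zero rows.
#' @export
extract_segments <- function(log, min_duration_s = 30, deadband = 2,
                             merge_tol_s = 1) {
  moving <- detect_motion(log, deadband)
  n <- length(moving)
  rate <- log$sample_rate_hz
  if (!any(moving)) {
    return(data.frame(start_t = numeric(0), end_t = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      duration_s = numeric(0)))
  }
  # bridge stationary gaps shorter than the merge tolerance
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bridged <- moving
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] && i > 1L && i < length(r$lengths) &&
        r$lengths[i] / rate < merge_tol_s) {
      bridged[starts[i]:ends[i]] <- TRUE
    }
  }
  r2 <- rle(bridged)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  keep <- r2$values & (r2$lengths / rate >= min_duration_s)
  t <- log$samples$t
  data.frame(
    start_t = t[starts2[keep]],
    end_t = t[ends2[keep]],
    start_idx = starts2[keep],
    end_idx = ends2[keep],
    duration_s = r2$lengths[keep] / rate
  )
}

#' Collision rates per hour
#'
#' Accidental-collision rates normalised by occupancy time ("hours in the
#' chair") and by actual driving time. Counts are kept exact; rounding is
#' left to presentation.
#'
#' @param events data.frame with a `kind` column (`"accidental"` /
#'   `"deliberate"`), e.g. the `events` element of a [joystick_log].
#' @param hours_in_chair,hours_driving exposure denominators, hours. Either
#'   may be `NA` to skip that rate; a zero denominator with a nonzero request
#'   is an error.
#' @return A list with `n_accidental`, `n_deliberate`, `per_chair_hour` and
#'   `per_driving_hour`.
#' @examples
#' ev <- data.frame(kind = rep("accidental", 10))
#' collision_rates(ev, hours_in_chair = NA, hours_driving = 2)$per_driving_hour
#' @export
collision_rates <- function(events, hours_in_chair = NA, hours_driving = NA) {
  n_acc <- if (is.null(events) || nrow(events) == 0L) 0L else sum(events$kind == "accidental")
  n_del <- if (is.null(events) || nrow(events) == 0L) 0L else sum(events$kind == "deliberate")
  rate_for <- function(hours) {
    if (is.na(hours)) return(NA_real_)
    if (hours <= 0) stop("hours must be > 0 for a requested rate")
    n_acc / hours
  }
  list(n_accidental = n_acc, n_deliberate = n_del,
       per_chair_hour = rate_for(hours_in_chair),
       per_driving_hour = rate_for(hours_driving))
}
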