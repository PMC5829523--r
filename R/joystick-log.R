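#' Construct a joystick telemetry log
#'
#' A `joystick_log` holds one run (or one day) of powered-wheelchair joystick
#' telemetry sampled from the wheelchair data bus: timestamped speed/turn axis
#' counts, optional drive-profile ids, optional IMU channels (stored opaquely,
#' never analysed), collision button events and obstacle proximity scans.
#'
#' Joystick axes are signed 8-bit counts in \[-128, 127\] with 0 = neutral:
#' `speed` is the forward/reverse axis (forward positive), `turn` the
#' left/right axis (right positive). Timestamps are integer milliseconds since
#' the start of the log and must be strictly increasing; the nominal sample
#' rate (50 Hz on the stock bus) is stored separately and never inferred.
#'
#' @param t integer milliseconds since log start, strictly increasing.
#' @param speed,turn signed joystick axis counts in \[-128, 127\].
#' @param profile small non-negative integer drive-profile id (recycled).
#' @param events optional data.frame of collision button presses with columns
#'   `t` (ms) and `kind` (`"accidental"` or `"deliberate"`).
#' @param scans optional [proximity_scans] object.
#' @param imu optional opaque IMU channel block (kept as-is).
#' @param sample_rate_hz nominal bus sample rate, Hz.
#' @param meta named list of identifier/date labels.
#' @return An object of class `joystick_log`: a list with elements `samples`
#'   (data.frame `t`, `speed`, `turn`, `profile`), `events`, `scans`, `imu`,
#'   `sample_rate_hz` and `meta`.
#' @examples
#' log <- joystick_log(t = c(0, 20, 40), speed = c(0, 50, 60), turn = c(0, -3, 4))
#' log$samples
#' @export
joystick_log <- function(t, speed, turn, profile = 0L, events = NULL,
                         scans = NULL, imu = NULL, sample_rate_hz = 50,
                         meta = list()) {
  samples <- data.frame(
    t = as.numeric(t),
    speed = as.numeric(speed),
    turn = as.numeric(turn),
    profile = as.integer(rep_len(profile, length(t)))
  )
  out <- structure(
    list(samples = samples, events = events, scans = scans, imu = imu,
         sample_rate_hz = sample_rate_hz, meta = meta),
    class = "joystick_log"
  )
  validate_joystick_log(out)
}

#' Validate a joystick log
#'
#' Checks the telemetry invariants: strictly increasing time, axis counts in
#' \[-128, 127\], positive sample rate, and event/scan timestamps inside the
#' sample time span. Errors name the first offending row.
#'
#' @param log a [joystick_log].
#' @return The validated log, invisibly unchanged.
#' @export
validate_joystick_log <- function(log) {
  s <- log$samples
  if (nrow(s) == 0L) stop("joystick_log has no samples")
  bad_t <- which(diff(s$t) <= 0)
  if (length(bad_t) > 0L) {
    stop(sprintf("non-monotonic time at row %d (t = %s after t = %s)",
                 bad_t[1] + 1L, format(s$t[bad_t[1] + 1L]), format(s$t[bad_t[1]])))
  }
  for (ax in c("speed", "turn")) {
    bad <- which(s[[ax]] < -128 | s[[ax]] > 127 | !is.finite(s[[ax]]))
    if (length(bad) > 0L) {
      stop(sprintf("%s out of [-128, 127] at row %d (value %s)",
                   ax, bad[1], format(s[[ax]][bad[1]])))
    }
  }
  if (!is.numeric(log$sample_rate_hz) || log$sample_rate_hz <= 0) {
    stop("sample_rate_hz must be > 0")
  }
  span <- range(s$t)
  if (!is.null(log$events) && nrow(log$events) > 0L) {
    if (!all(log$events$kind %in% c("accidental", "deliberate"))) {
      stop("collision event kind must be 'accidental' or 'deliberate'")
    }
    if (any(log$events$t < span[1] | log$events$t > span[2])) {
      stop("collision event timestamp outside sample time span")
    }
  }
  if (!is.null(log$scans)) {
    st <- log$scans$t
    if (any(st < span[1] | st > span[2])) {
      stop("proximity scan timestamp outside sample time span")
    }
  }
  invisible(log)
}

#' @export
print.joystick_log <- function(x, ...) {
  s <- x$samples
  dur <- (s$t[nrow(s)] - s$t[1]) / 1000
  cat(sprintf("<joystick_log> %d samples, %.1f s at %g Hz nominal\n",
              nrow(s), dur, x$sample_rate_hz))
  cat(sprintf("  speed in [%g, %g], turn in [%g, %g]\n",
              min(s$speed), max(s$speed), min(s$turn), max(s$turn)))
  if (!is.null(x$events)) cat(sprintf("  %d collision events\n", nrow(x$events)))
  if (!is.null(x$scans)) {
    cat(sprintf("  %d proximity scans x %d sectors\n",
                nrow(x$scans$ranges), ncol(x$scans$ranges)))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a set of obstacle proximity scans
#'
#' One range reading per angular sector around the platform per scan instant,
#' in the body frame: 0 degrees is straight ahead, bearings increase clockwise
#' (positive = right of the platform).
#'
#' @param t scan timestamps, milliseconds.
#' @param ranges numeric matrix, one row per scan, one column per sector;
#'   obstacle distance in metres (sensor maximum where nothing is seen).
#' @param sector_angles sector centre bearings, degrees body frame; length
#'   must match `ncol(ranges)`. Default: 8 sectors at 45 degree spacing.
#' @return An object of class `proximity_scans`.
#' @export
proximity_scans <- function(t, ranges, sector_angles = seq(0, 315, by = 45)) {
  ranges <- as.matrix(ranges)
  if (length(t) != nrow(ranges)) stop("length(t) must equal nrow(ranges)")
  if (length(sector_angles) != ncol(ranges)) {
    stop("sector_angles length must equal the sector count")
  }
  if (any(ranges < 0, na.rm = TRUE)) stop("ranges must be >= 0")
  structure(list(t = as.numeric(t), ranges = ranges,
                 sector_angles = as.numeric(sector_angles)),
            class = "proximity_scans")
}

# Canonical CSV dialect: header row, comma separated, UTF-8.
log_columns <- c("t_ms", "speed", "turn", "profile", "ax", "ay", "az",
                 "roll", "pitch", "yaw", "collision")

#' Read a joystick telemetry log from CSV
#'
#' The dialect mirrors the deposited bus recordings: columns `t_ms`, `speed`,
#' `turn`, `profile`, six IMU channels (`ax ay az roll pitch yaw`, stored but
#' not analysed) and `collision` (0 = none, 1 = accidental button,
#' 2 = deliberate button). Only `t_ms`, `speed` and `turn` are mandatory.
#' Malformed rows are rejected with the offending row number, never dropped.
#'
#' @param path CSV file path.
#' @param scans_path optional companion CSV of proximity scans with columns
#'   `t_ms, sector_0..sector_{n-1}` (sector bearings at 360/n degree spacing).
#' @param sample_rate_hz nominal rate to record on the log.
#' @return A validated [joystick_log].
#' @seealso [write_joystick_log()]
#' @export
read_joystick_log <- function(path, scans_path = NULL, sample_rate_hz = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_ms", "speed", "turn")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[col]]))))
    if (length(bad) > 0L) {
      stop(sprintf("malformed value in column '%s' at data row %d", col, bad[1]))
    }
  }
  imu_cols <- intersect(c("ax", "ay", "az", "roll", "pitch", "yaw"), names(d))
  imu <- if (length(imu_cols)) d[imu_cols] else NULL
  events <- NULL
  if ("collision" %in% names(d)) {
    hit <- which(d$collision != 0)
    if (length(hit) > 0L) {
      events <- data.frame(
        t = as.numeric(d$t_ms[hit]),
        kind = ifelse(d$collision[hit] == 2, "deliberate", "accidental")
      )
    }
  }
  scans <- if (!is.null(scans_path)) read_proximity_scans(scans_path) else NULL
  profile <- if ("profile" %in% names(d)) d$profile else 0L
  joystick_log(t = d$t_ms, speed = d$speed, turn = d$turn, profile = profile,
               events = events, scans = scans, imu = imu,
               sample_rate_hz = sample_rate_hz,
               meta = list(source = basename(path)))
}

#' Read a proximity scan CSV
#'
#' @param path CSV with columns `t_ms, sector_0..sector_{n-1}`.
#' @return A [proximity_scans] object; sector bearings are taken as evenly
#'   spaced clockwise from 0 degrees (forward).
#' @export
read_proximity_scans <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"t_ms" %in% names(d)) stop("missing required column: t_ms")
  sec <- grep("^sector_", names(d), value = TRUE)
  if (length(sec) == 0L) stop("no sector_* columns found")
  sec <- sec[order(as.integer(sub("^sector_", "", sec)))]
  n <- length(sec)
  proximity_scans(t = d$t_ms, ranges = as.matrix(d[sec]),
                  sector_angles = seq(0, 360 - 360 / n, by = 360 / n))
}

#' Write a joystick log to canonical CSV
#'
#' Inverse of [read_joystick_log()]: writing then re-reading a log reproduces
#' it exactly (the canonical dialect carries integer milliseconds and counts).
#'
#' @param log a [joystick_log].
#' @param path output CSV path.
#' @param scans_path optional path for the companion proximity-scan CSV.
#' @return `path`, invisibly.
#' @export
write_joystick_log <- function(log, path, scans_path = NULL) {
  s <- log$samples
  d <- data.frame(t_ms = s$t, speed = s$speed, turn = s$turn,
                  profile = s$profile)
  for (col in c("ax", "ay", "az", "roll", "pitch", "yaw")) {
    d[[col]] <- if (!is.null(log$imu) && col %in% names(log$imu)) log$imu[[col]] else 0
  }
  d$collision <- 0L
  if (!is.null(log$events) && nrow(log$events) > 0L) {
    idx <- findInterval(log$events$t, s$t)
    d$collision[idx] <- ifelse(log$events$kind == "deliberate", 2L, 1L)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (!is.null(scans_path) && !is.null(log$scans)) {
    sc <- as.data.frame(log$scans$ranges)
    names(sc) <- paste0("sector_", seq_len(ncol(sc)) - 1L)
    utils::write.csv(cbind(t_ms = log$scans$t, sc), scans_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
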