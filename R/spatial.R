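quadrant_labels <- c("forward_left", "forward_right", "rear_left", "rear_right")

#' Assign joystick samples to input quadrants
#'
#' The joystick plane is split into four quadrants (forward/rear x left/right).
#' Samples inside the deadband are neutral. Boundary convention: forward iff
#' `speed > 0` (pure turning at `speed == 0` counts as forward), left iff
#' `turn < 0` (`turn == 0` counts as right).
#'
#' @param speed,turn joystick axis counts (vectorised).
#' @param deadband neutral threshold, counts.
#' @return Character vector: one of `"forward_left"`, `"forward_right"`,
#'   `"rear_left"`, `"rear_right"` or `NA` for neutral samples.
#' @export
assign_quadrant <- function(speed, turn, deadband = 2) {
  neutral <- pmax(abs(speed), abs(turn)) <= deadband
  fr <- ifelse(speed > 0 | (speed == 0 & abs(turn) > deadband), "forward", "rear")
  lr <- ifelse(turn < 0, "left", "right")
  out <- paste(fr, lr, sep = "_")
  out[neutral] <- NA_character_
  out
}

# quartiles by linear interpolation between order statistics (type 7)
q147 <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)

#' Per-quadrant joystick position bias ellipse
#'
#' Summarises where in each quadrant the user holds the joystick, as an
#' ellipse in the (turn, speed) plane: semi-axis `A` (turn, x axis) is the
#' interquartile range of in-quadrant `|turn|`, semi-axis `B` (speed, y axis)
#' the interquartile range of in-quadrant `|speed|`; the x-axis centre `cx` is
#' the median turn value and the y-axis centre `cy` the first quartile of the
#' speed values. Quadrants holding fewer than `min_samples` non-neutral
#' samples are flagged empty rather than estimated.
#'
#' @param samples data.frame with `speed` and `turn` columns (counts).
#' @param deadband neutral threshold, counts.
#' @param min_samples minimum in-quadrant samples for an estimate.
#' @return An object of class `ellipse_bias`: a data.frame with one row per
#'   quadrant and columns `quadrant`, `A`, `B`, `cx`, `cy`, `n`, `empty`.
#' @export
position_ellipse <- function(samples, deadband = 2, min_samples = 4) {
  q <- assign_quadrant(samples$speed, samples$turn, deadband)
  rows <- lapply(quadrant_labels, function(lab) {
    idx <- which(!is.na(q) & q == lab)
    if (length(idx) < min_samples) {
      return(data.frame(quadrant = lab, A = NA_real_, B = NA_real_,
                        cx = NA_real_, cy = NA_real_,
                        n = length(idx), empty = TRUE))
    }
    turn <- samples$turn[idx]
    speed <- samples$speed[idx]
    qt <- q147(abs(turn))
    qs <- q147(abs(speed))
    data.frame(quadrant = lab,
               A = qt[3] - qt[1],
               B = qs[3] - qs[1],
               cx = stats::median(turn),
               cy = stats::quantile(speed, 0.25, names = FALSE, type = 7),
               n = length(idx), empty = FALSE)
  })
  structure(do.call(rbind, rows), class = c("ellipse_bias", "data.frame"))
}

#' Per-quadrant joystick velocity-vector bias
#'
#' The per-step joystick velocity-vector magnitude (see
#' [smoothness_lambda()]) is assigned to the quadrant of the later sample of
#' each step, and summarised per quadrant by its quartiles (the middle-50%
#' range). A throw calibration converts counts/s to mm/s; the default
#' 0.2 mm/count corresponds to a 25 mm full throw spanning 127 counts.
#'
#' @param samples data.frame with `t` (ms), `speed`, `turn` columns.
#' @param counts_to_mm calibration factor, mm per count.
#' @param deadband neutral threshold for quadrant assignment, counts.
#' @return An object of class `velocity_bias`: a data.frame with one row per
#'   quadrant and columns `quadrant`, `q1`, `median`, `q3` (mm/s), `n`.
#' @export
velocity_vector_bias <- function(samples, counts_to_mm = 0.2, deadband = 2) {
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  dt <- diff(samples$t) / 1000
  lam <- sqrt(diff(samples$speed)^2 + diff(samples$turn)^2) / dt
  q <- assign_quadrant(samples$speed, samples$turn, deadband)[-1L]
  rows <- lapply(quadrant_labels, function(lab) {
    lam_q <- lam[!is.na(q) & q == lab]
    if (length(lam_q) == 0L) {
      return(data.frame(quadrant = lab, q1 = 0, median = 0, q3 = 0, n = 0L))
    }
    qq <- q147(lam_q) * counts_to_mm
    data.frame(quadrant = lab, q1 = qq[1], median = qq[2], q3 = qq[3],
               n = length(lam_q))
  })
  structure(do.call(rbind, rows), class = c("velocity_bias", "data.frame"))
}

#' Linear remapping specification
#'
#' Describes a linear map from a source interval (`in_min`, width `range_in`)
#' onto a target interval (`out_min`, width `range_out`), used both for
#' re-shaping joystick throw and for placing the damping curve onto its
#' multiplier range.
#'
#' @param in_min,range_in source interval start and width; `range_in != 0`.
#' @param out_min,range_out target interval start and width.
#' @param clamp clamp outputs to the target interval?
#' @return A list of class `remap_spec`.
#' @export
remap_spec <- function(in_min, range_in, out_min, range_out, clamp = FALSE) {
  if (range_in == 0) stop("range_in must be nonzero")
  structure(list(in_min = in_min, range_in = range_in, out_min = out_min,
                 range_out = range_out, clamp = clamp),
            class = "remap_spec")
}

#' Apply a linear remap
#'
#' `x_out = (x_in - in_min) * range_out / range_in + out_min`, optionally
#' clamped to the target interval. Affine, so midpoints are preserved, and
#' composing a spec with its inverse is the identity.
#'
#' @param x_in numeric values.
#' @param spec a [remap_spec].
#' @return Remapped values.
#' @export
remap_value <- function(x_in, spec) {
  out <- (x_in - spec$in_min) * spec$range_out / spec$range_in + spec$out_min
  if (isTRUE(spec$clamp)) {
    lo <- min(spec$out_min, spec$out_min + spec$range_out)
    hi <- max(spec$out_min, spec$out_min + spec$range_out)
    out <- pmin(pmax(out, lo), hi)
  }
  out
}

#' Invert a remap specification
#' @param spec a [remap_spec].
#' @return The inverse [remap_spec].
#' @export
invert_remap <- function(spec) {
  if (spec$range_out == 0) stop("cannot invert a spec with zero range_out")
  remap_spec(spec$out_min, spec$range_out, spec$in_min, spec$range_in)
}

#' Derive per-quadrant remap specs from observed and target ellipses
#'
#' For each quadrant and axis, maps the user's observed interval
#' (centre +/- semi-axis) onto the corresponding target interval, so that a
#' user with compressed or off-centre throw is stretched back onto the
#' intended pattern. Degenerate user quadrants (zero spread or flagged empty)
#' yield identity pass-through specs, flagged.
#'
#' @param user,target [position_ellipse()] results.
#' @return A named list (by quadrant) of lists with elements `x` and `y`
#'   ([remap_spec]s for the turn and speed axes) and `passthrough`.
#' @export
derive_remap_from_ellipse <- function(user, target) {
  out <- lapply(quadrant_labels, function(lab) {
    u <- user[user$quadrant == lab, ]
    tg <- target[target$quadrant == lab, ]
    if (tg$empty || tg$A == 0 || tg$B == 0) {
      stop("target quadrant ", lab, " is degenerate")
    }
    if (u$empty || is.na(u$A) || u$A == 0 || u$B == 0) {
      return(list(x = remap_spec(0, 1, 0, 1), y = remap_spec(0, 1, 0, 1),
                  passthrough = TRUE))
    }
    list(
      x = remap_spec(u$cx - u$A, 2 * u$A, tg$cx - tg$A, 2 * tg$A),
      y = remap_spec(u$cy - u$B, 2 * u$B, tg$cy - tg$B, 2 * tg$B),
      passthrough = FALSE
    )
  })
  names(out) <- quadrant_labels
  out
}

#' Apply per-quadrant remap specs to joystick samples
#'
#' Each non-neutral sample is remapped by its quadrant's axis specs (turn via
#' `x`, speed via `y`); neutral samples and pass-through quadrants are left
#' unchanged. Outputs are clipped to the signed 8-bit count range.
#'
#' @param samples data.frame with `speed` and `turn` columns.
#' @param specs result of [derive_remap_from_ellipse()].
#' @param deadband neutral threshold, counts.
#' @return The samples with remapped `speed`/`turn`.
#' @export
apply_remap <- function(samples, specs, deadband = 2) {
  q <- assign_quadrant(samples$speed, samples$turn, deadband)
  out <- samples
  for (lab in quadrant_labels) {
    sp <- specs[[lab]]
    if (isTRUE(sp$passthrough)) next
    idx <- which(!is.na(q) & q == lab)
    if (length(idx) == 0L) next
    out$turn[idx] <- remap_value(samples$turn[idx], sp$x)
    out$speed[idx] <- remap_value(samples$speed[idx], sp$y)
  }
  out$turn <- pmin(pmax(out$turn, -128), 127)
  out$speed <- pmin(pmax(out$speed, -128), 127)
  out
}
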