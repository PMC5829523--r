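#' DLAFF ellipse geometry
#'
#' One of the two travelling ellipses of the Dynamic Localised Adjustable
#' Force Field. One focus is pinned at the body origin `O` (the midpoint of
#' the rear drive axle); the second focus `F` is constrained to the body X
#' axis (forward positive), at distance `focus_f` from `O`. `semi_major` is
#' half the major-axis length. An optional `lateral_extension` widens the
#' ellipse along the body Y axis only, extending the repulsive zone to the
#' sides without moving the front/rear reach.
#'
#' @param semi_major semi-major axis, metres; must exceed `focus_f / 2` so the
#'   ellipse is non-degenerate.
#' @param focus_f signed distance of the second focus along body X, metres.
#' @param lateral_extension additional sideways reach, metres.
#' @return A list of class `dlaff_ellipse`.
#' @export
dlaff_ellipse <- function(semi_major, focus_f = 0, lateral_extension = 0) {
  if (semi_major <= abs(focus_f) / 2) {
    stop("degenerate ellipse: semi_major must exceed |focus_f| / 2")
  }
  if (lateral_extension < 0) stop("lateral_extension must be >= 0")
  structure(list(semi_major = semi_major, focus_f = focus_f,
                 lateral_extension = lateral_extension),
            class = "dlaff_ellipse")
}

#' DLAFF configuration
#'
#' Inner and outer damping ellipses plus the damping-shape constant. The
#' inner ellipse should enclose the platform (and user) footprint; the outer
#' ellipse bounds the zone in which wheel commands are damped. `k` controls
#' how sharply the damping rises as an obstacle penetrates the gap: smaller
#' `k` keeps full speed until closer in, then drops steeply (less safety
#' margin); larger `k` backs off earlier. `k = NULL` (default) uses a quarter
#' of the radial gap on each bearing.
#'
#' @param inner,outer [dlaff_ellipse]s; the outer must strictly contain the
#'   inner along every radial (checked numerically).
#' @param k damping-shape constant, metres, or `NULL` for `(R - p) / 4`.
#' @param floor minimum damping multiplier, in (0, 1).
#' @param wheel_base_w distance between the rear drive wheels, metres.
#' @return A list of class `dlaff_config`.
#' @export
dlaff_config <- function(inner = dlaff_ellipse(0.8, 0.5),
                         outer = dlaff_ellipse(2.0, 0.8),
                         k = NULL, floor = 0.01, wheel_base_w = 0.5) {
  if (floor <= 0 || floor >= 1) stop("floor must be in (0, 1)")
  if (!is.null(k) && k <= 0) stop("k must be > 0")
  if (wheel_base_w <= 0) stop("wheel_base_w must be > 0")
  cfg <- structure(list(inner = inner, outer = outer, k = k, floor = floor,
                        wheel_base_w = wheel_base_w),
                   class = "dlaff_config")
  br <- seq(0, 359, by = 1)
  d <- vapply(br, function(b) unlist(radial_distances(cfg, b)), numeric(2))
  if (any(d[2, ] <= d[1, ])) {
    stop("outer ellipse must strictly contain the inner along every radial")
  }
  cfg
}

# distance from the origin focus to an ellipse along unit direction u,
# via the focal-chord closed form: t + |t*u - F| = 2a
ellipse_radial <- function(ellipse, bearing_deg) {
  th <- bearing_deg * pi / 180
  u <- c(cos(th), sin(th))  # x forward, y right (bearings clockwise positive)
  a <- ellipse$semi_major
  f <- c(ellipse$focus_f, 0)
  t <- (4 * a^2 - sum(f^2)) / (4 * a - 2 * sum(u * f))
  t + ellipse$lateral_extension * abs(u[2])
}

#' Radial distances to the inner and outer DLAFF ellipses
#'
#' Intersection distances of a ray cast from the body origin `O` along a
#' given bearing (degrees, body frame; 0 = forward, positive clockwise) with
#' the inner ellipse (`p`) and the outer ellipse (`R`).
#'
#' @param cfg a [dlaff_config].
#' @param bearing_deg bearing, degrees body frame.
#' @return List with `p` and `R`, metres, `R > p`.
#' @export
radial_distances <- function(cfg, bearing_deg) {
  list(p = ellipse_radial(cfg$inner, bearing_deg),
       R = ellipse_radial(cfg$outer, bearing_deg))
}

#' Damping multiplier for an obstacle at a given distance
#'
#' Obstacles beyond the outer ellipse leave motion untouched (multiplier 1);
#' at or inside the inner ellipse motion is floored at the minimum multiplier.
#' In between, the damping follows the exponential force curve
#' `1 - exp(-(d - p)/k)` evaluated over the gap and linearly remapped so its
#' attained range spans exactly `[floor, 1]` across `[p, R]`. The result is
#' continuous and monotone non-decreasing in obstacle distance.
#'
#' @param d_obstacle obstacle distance along the radial, metres (vectorised).
#' @param p,R inner/outer radial distances, metres, `R > p`.
#' @param k damping-shape constant, metres; `NULL` for `(R - p) / 4`.
#' @param floor minimum multiplier.
#' @return Multiplier(s) in `[floor, 1]`.
#' @examples
#' damping_factor(2, p = 0.8, R = 2, k = 0.3)   # at the outer ellipse: 1
#' damping_factor(0.5, p = 0.8, R = 2, k = 0.3) # inside the inner: 0.01
#' @export
damping_factor <- function(d_obstacle, p, R, k = NULL, floor = 0.01) {
  if (R <= p) stop("R must be greater than p")
  if (any(d_obstacle < 0)) stop("d_obstacle must be >= 0")
  if (is.null(k)) k <- (R - p) / 4
  raw <- function(d) 1 - exp(-(d - p) / k)
  # remap the curve's attained range over [p, R] onto [floor, 1]
  spec <- remap_spec(in_min = raw(p), range_in = raw(R) - raw(p),
                     out_min = floor, range_out = 1 - floor, clamp = TRUE)
  out <- remap_value(raw(pmin(pmax(d_obstacle, p), R)), spec)
  out[d_obstacle >= R] <- 1
  out[d_obstacle <= p] <- floor
  out
}

#' Differential-drive kinematics
#'
#' Body velocities from individual rear-wheel velocities:
#' `v = (v_right + v_left) / 2`, `omega = (v_right - v_left) / W`. With wheel
#' speeds bounded by a common limit, the ratio of maximum rotation rate to
#' maximum forward velocity is `2 / W` -- a 0.5 m wheel base turns 4 times
#' faster than it drives; only at `W = 2` m are the two proportional.
#'
#' @param v_right,v_left rear wheel velocities, m/s.
#' @param w wheel separation, metres.
#' @return List with `v` (m/s) and `omega` (rad/s).
#' @seealso [inverse_kinematics()]
#' @export
kinematics <- function(v_right, v_left, w) {
  if (w <= 0) stop("wheel separation w must be > 0")
  list(v = (v_right + v_left) / 2, omega = (v_right - v_left) / w)
}

#' Inverse differential-drive kinematics
#'
#' Wheel velocities realising a commanded body velocity pair:
#' `v_right = v + w * omega / 2`, `v_left = v - w * omega / 2`. Exact inverse
#' of [kinematics()].
#'
#' @param v body forward velocity, m/s.
#' @param omega body rotation rate, rad/s.
#' @param w wheel separation, metres.
#' @return List with `v_right` and `v_left`, m/s.
#' @export
inverse_kinematics <- function(v, omega, w) {
  if (w <= 0) stop("wheel separation w must be > 0")
  list(v_right = v + w * omega / 2, v_left = v - w * omega / 2)
}

# joystick counts <-> virtual wheel signals. The joystick obeys the same
# mixing as the platform with an effective wheel base of 2 units, making the
# speed and turn axes equally proportional: right = speed + turn,
# left = speed - turn.
joystick_to_wheels <- function(speed, turn) {
  list(right = speed + turn, left = speed - turn)
}
wheels_to_joystick <- function(right, left) {
  list(speed = (right + left) / 2, turn = (right - left) / 2)
}

#' Apply DLAFF damping to a joystick command
#'
#' Converts the joystick command to virtual wheel signals, damps each wheel by
#' the multiplier of the nearest obstacle in the *opposite* forward sector
#' (the cross rule: a forward-right obstacle damps the left wheel, steering
#' the platform right, away from its own heading into the obstacle -- i.e.
#' the chair yaws away from the blocked side), and converts back. When the
#' commanded motion is reverse, the same rule is applied mirrored to the rear
#' sectors. Wheel signal signs are preserved and magnitudes never increase.
#'
#' @param speed,turn joystick command, counts.
#' @param scan_ranges per-sector obstacle distances (one scan), metres.
#' @param sector_angles sector centre bearings, degrees body frame.
#' @param cfg a [dlaff_config].
#' @return List of class `damping_result`: corrected `speed`/`turn`,
#'   `left_multiplier`, `right_multiplier`, and `active_sectors` (indices of
#'   the sector that set each multiplier: `left`, `right`).
#' @export
apply_damping <- function(speed, turn, scan_ranges, sector_angles, cfg) {
  if (is.null(scan_ranges) || length(scan_ranges) == 0L) {
    warning("no scan data: joystick command passed through undamped")
    return(structure(list(speed = speed, turn = turn, left_multiplier = 1,
                          right_multiplier = 1,
                          active_sectors = list(left = NA, right = NA)),
                     class = "damping_result"))
  }
  b <- ((sector_angles + 180) %% 360) - 180  # to (-180, 180]
  reversing <- speed < 0
  if (!reversing) {
    right_half <- which(b > 0 & b < 90)
    left_half <- which(b < 0 & b > -90)
    ahead <- which(b == 0)
  } else {
    right_half <- which(b > 90 & b < 180)
    left_half <- which(b < -90 & b > -180)
    ahead <- which(abs(b) == 180)
  }
  # straight-ahead (or straight-behind) sector threatens both wheels
  right_half <- c(right_half, ahead)
  left_half <- c(left_half, ahead)
  mult_for <- function(sectors) {
    if (length(sectors) == 0L) return(list(m = 1, sector = NA))
    i <- sectors[which.min(scan_ranges[sectors])]
    pr <- radial_distances(cfg, sector_angles[i])
    list(m = damping_factor(scan_ranges[i], pr$p, pr$R, cfg$k, cfg$floor),
         sector = i)
  }
  near_right <- mult_for(right_half)  # damps LEFT wheel
  near_left <- mult_for(left_half)    # damps RIGHT wheel
  if (near_right$m == 1 && near_left$m == 1) {
    return(structure(list(speed = speed, turn = turn, left_multiplier = 1,
                          right_multiplier = 1,
                          active_sectors = list(left = near_right$sector,
                                                right = near_left$sector)),
                     class = "damping_result"))
  }
  wh <- joystick_to_wheels(speed, turn)
  corrected <- wheels_to_joystick(right = wh$right * near_left$m,
                                  left = wh$left * near_right$m)
  structure(list(speed = corrected$speed, turn = corrected$turn,
                 left_multiplier = near_right$m,
                 right_multiplier = near_left$m,
                 active_sectors = list(left = near_right$sector,
                                       right = near_left$sector)),
            class = "damping_result")
}

#' Apply DLAFF damping along a whole log
#'
#' Runs [apply_damping()] over every sample of a log, holding the most recent
#' proximity scan (zero-order hold). Samples before the first scan are passed
#' through.
#'
#' @param log a [joystick_log] with `scans`.
#' @param cfg a [dlaff_config].
#' @return A list with `corrected` (data.frame `t`, `speed`, `turn`) and
#'   `multipliers` (data.frame `left`, `right`).
#' @export
damp_log <- function(log, cfg) {
  if (is.null(log$scans)) stop("log has no proximity scans")
  s <- log$samples
  scan_idx <- findInterval(s$t, log$scans$t)
  n <- nrow(s)
  out_speed <- s$speed
  out_turn <- s$turn
  ml <- rep(1, n)
  mr <- rep(1, n)
  for (i in seq_len(n)) {
    if (scan_idx[i] == 0L) next
    r <- apply_damping(s$speed[i], s$turn[i],
                       log$scans$ranges[scan_idx[i], ],
                       log$scans$sector_angles, cfg)
    out_speed[i] <- r$speed
    out_turn[i] <- r$turn
    ml[i] <- r$left_multiplier
    mr[i] <- r$right_multiplier
  }
  list(corrected = data.frame(t = s$t, speed = out_speed, turn = out_turn),
       multipliers = data.frame(left = ml, right = mr))
}

#' Obstacle-proximity bias feature
#'
#' How much, and where, the collision-avoidance layer had to intervene: the
#' per-sample magnitude of the difference between the user's joystick input
#' and the system-corrected input, moving-averaged over a short window, then
#' summarised per quadrant (of the user's input) by the median of the
#' windowed values. Zero everywhere means the user never needed correction.
#'
#' @param user data.frame `t`, `speed`, `turn` -- the raw input.
#' @param corrected data.frame `t`, `speed`, `turn` -- the damped input,
#'   aligned sample-for-sample with `user`.
#' @param window_s moving-average window, seconds.
#' @param sample_rate_hz sample rate, Hz.
#' @param deadband neutral threshold for quadrant assignment, counts.
#' @return Named numeric vector of per-quadrant bias magnitudes (counts), in
#'   the order forward_left, forward_right, rear_left, rear_right.
#' @export
proximity_bias_feature <- function(user, corrected, window_s = 1,
                                   sample_rate_hz = 50, deadband = 2) {
  if (nrow(user) != nrow(corrected) || any(user$t != corrected$t)) {
    stop("user and corrected traces are misaligned")
  }
  diff_mag <- sqrt((user$speed - corrected$speed)^2 +
                     (user$turn - corrected$turn)^2)
  w <- max(1L, round(window_s * sample_rate_hz))
  avg <- as.numeric(zoo::rollmean(zoo::zoo(diff_mag), k = min(w, length(diff_mag)),
                                  fill = NA, align = "center"))
  q <- assign_quadrant(user$speed, user$turn, deadband)
  out <- vapply(quadrant_labels, function(lab) {
    v <- avg[!is.na(q) & q == lab & !is.na(avg)]
    if (length(v) == 0L) 0 else stats::median(v)
  }, numeric(1))
  names(out) <- quadrant_labels
  out
}
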