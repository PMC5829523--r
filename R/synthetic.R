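#' User driving archetype
#'
#' Generative description of a simulated joystick user, operationalising the
#' symptom-to-measurement mapping the feature set is built on: where in each
#' quadrant they hold the stick (`ellipse_target`), an injected quasi-
#' sinusoidal tremor (frequency 0 = none, otherwise typically 4-11 Hz),
#' high-frequency jitter feeding the smoothness score, per-quadrant movement
#' rate scalers, the target motion/stationary ratio, and an optional per-day
#' multiplicative drift applied to the severity parameters.
#'
#' @param ellipse_target data.frame like a [position_ellipse()] result
#'   (columns `quadrant`, `A`, `B`, `cx`, `cy`): the intended throw pattern.
#' @param tremor_hz tremor frequency, Hz; 0 disables.
#' @param tremor_amp tremor amplitude, counts.
#' @param smooth_noise jitter magnitude feeding the smoothness score,
#'   counts/s.
#' @param vel_bias named per-quadrant movement-rate scalers.
#' @param stop_drive_ratio target moving/stationary time ratio.
#' @param drift_per_day multiplicative per-day change applied to
#'   `tremor_amp` and `smooth_noise` (1 = stable user).
#' @param quadrant_weights named occupancy weights over the four quadrants.
#' @return A list of class `user_archetype`.
#' @export
user_archetype <- function(ellipse_target = default_ellipse_target(),
                           tremor_hz = 0, tremor_amp = 0,
                           smooth_noise = 50,
                           vel_bias = c(forward_left = 1, forward_right = 1,
                                        rear_left = 1, rear_right = 1),
                           stop_drive_ratio = 1.5,
                           drift_per_day = 1,
                           quadrant_weights = c(forward_left = 0.3,
                                                forward_right = 0.3,
                                                rear_left = 0.2,
                                                rear_right = 0.2)) {
  if (!(tremor_hz == 0 || (tremor_hz >= 0.5 && tremor_hz <= 15))) {
    stop("tremor_hz must be 0 or within the analysable 0.5-15 Hz band")
  }
  stopifnot(tremor_amp >= 0, smooth_noise >= 0, stop_drive_ratio > 0,
            drift_per_day > 0)
  structure(list(ellipse_target = ellipse_target, tremor_hz = tremor_hz,
                 tremor_amp = tremor_amp, smooth_noise = smooth_noise,
                 vel_bias = vel_bias, stop_drive_ratio = stop_drive_ratio,
                 drift_per_day = drift_per_day,
                 quadrant_weights = quadrant_weights),
            class = "user_archetype")
}

#' Default intended throw pattern
#'
#' A plausible well-set-up pattern: forward quadrants centred at around half
#' forward throw with a wide speed spread, rear quadrants shallower, turn
#' centres offset into each quadrant so samples stay off the axes.
#'
#' @return A data.frame usable as `ellipse_target` in [user_archetype()].
#' @export
default_ellipse_target <- function() {
  data.frame(
    quadrant = c("forward_left", "forward_right", "rear_left", "rear_right"),
    A = c(15, 15, 12, 12),
    B = c(40, 40, 30, 30),
    cx = c(-25, 25, -20, 20),
    cy = c(60, 60, -50, -50)
  )
}

#' Simulate a joystick telemetry trace
#'
#' Renders an archetype into a 50 Hz telemetry log: driving bouts alternate
#' with stops so the moving/stationary ratio lands on the archetype's target
#' (within a few percent over a long enough trace); within a bout the stick
#' dwells on targets drawn uniformly from the quadrant's intended interval
#' (centre +/- semi-axis on each axis, so the extracted ellipse recovers the
#' target), with short ramps between dwell points, additive sinusoidal tremor
#' and Gaussian jitter. All outputs are clipped to \[-128, 127\] counts.
#'
#' @param archetype a [user_archetype].
#' @param duration_s trace length, seconds (>= 10).
#' @param sample_rate_hz sample rate, Hz.
#' @param seed RNG seed (NULL = use current RNG state).
#' @param day day index, applying `drift_per_day^(day - 1)` to the severity
#'   parameters.
#' @return A [joystick_log].
#' @export
simulate_trace <- function(archetype, duration_s, sample_rate_hz = 50,
                           seed = NULL, day = 1) {
  if (duration_s < 10) stop("duration_s must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  rate <- sample_rate_hz
  n <- round(duration_s * rate)
  drift <- archetype$drift_per_day^(day - 1)
  tremor_amp <- archetype$tremor_amp * drift
  jitter_sd <- archetype$smooth_noise * drift / rate

  speed <- numeric(n)
  turn <- numeric(n)
  moving <- logical(n)
  ell <- archetype$ellipse_target
  wts <- archetype$quadrant_weights

  i <- 1L
  while (i <= n) {
    drive_len <- round(stats::runif(1, 8, 12) * rate)
    stop_len <- round(drive_len / archetype$stop_drive_ratio *
                        stats::runif(1, 0.95, 1.05))
    # drive bout, split into phrases of a few seconds, each inside one
    # quadrant's box. Within a phrase each axis follows a slow triangle wave
    # spanning its interval: the triangle wave has an exactly uniform
    # marginal, so the extracted quartile geometry converges to the intended
    # ellipse at the sweep rate. A short ramp blends phrase boundaries.
    j <- i
    bout_end <- min(n, i + drive_len - 1L)
    tri <- function(ph) 2 * abs(2 * (ph - floor(ph + 0.5))) - 1  # in [-1, 1]
    while (j <= bout_end) {
      q <- sample(names(wts), 1, prob = wts)
      e <- ell[ell$quadrant == q, ]
      rate_scale <- archetype$vel_bias[[q]]
      phrase <- max(10L, round(stats::runif(1, 2, 4) * rate))
      seg_end <- min(bout_end, j + phrase - 1L)
      len <- seg_end - j + 1L
      ts <- seq_len(len) / rate
      f1 <- stats::runif(1, 0.25, 0.6) * rate_scale
      f2 <- stats::runif(1, 0.25, 0.6) * rate_scale
      new_turn <- e$cx + e$A * tri(f1 * ts + stats::runif(1))
      new_speed <- e$cy + e$B * tri(f2 * ts + stats::runif(1))
      ramp <- min(max(2L, round(0.1 * rate)), len)
      if (j > 1L) {
        blend <- seq(0, 1, length.out = ramp)
        new_turn[1:ramp] <- turn[j - 1L] * (1 - blend) + new_turn[1:ramp] * blend
        new_speed[1:ramp] <- speed[j - 1L] * (1 - blend) + new_speed[1:ramp] * blend
      }
      turn[j:seg_end] <- new_turn
      speed[j:seg_end] <- new_speed
      j <- seg_end + 1L
    }
    moving[i:bout_end] <- TRUE
    i <- bout_end + 1L
    if (i > n) break
    stop_end <- min(n, i + stop_len - 1L)
    speed[i:stop_end] <- 0
    turn[i:stop_end] <- 0
    i <- stop_end + 1L
  }

  t_s <- (seq_len(n) - 1L) / rate
  if (archetype$tremor_hz > 0 && tremor_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    trem_s <- tremor_amp * sin(2 * pi * archetype$tremor_hz * t_s + phase)
    trem_t <- 0.5 * tremor_amp * cos(2 * pi * archetype$tremor_hz * t_s + phase)
    speed[moving] <- speed[moving] + trem_s[moving]
    turn[moving] <- turn[moving] + trem_t[moving]
  }
  if (jitter_sd > 0) {
    speed[moving] <- speed[moving] + stats::rnorm(sum(moving), 0, jitter_sd)
    turn[moving] <- turn[moving] + stats::rnorm(sum(moving), 0, jitter_sd)
  }
  speed <- pmin(pmax(speed, -128), 127)
  turn <- pmin(pmax(turn, -128), 127)
  joystick_log(t = round(t_s * 1000), speed = speed, turn = turn,
               sample_rate_hz = rate,
               meta = list(synthetic = TRUE, day = day))
}

#' Generate the artificial-tremor calibration fixture set
#'
#' Emulates the bench calibration experiment: a set of artificial tremors,
#' each rendered twice -- a high-rate "analogue" path (about 250 Hz, as if
#' sampled directly from the joystick coils) and a "digital bus" path, the
#' same signal decimated to the 50 Hz wheelchair bus rate. The default 16
#' frequencies span 3-9 Hz.
#'
#' @param frequencies tremor frequencies, Hz, each in (0, 25).
#' @param seed RNG seed.
#' @param duration_s fixture length, seconds.
#' @param amp tremor amplitude, counts.
#' @param noise_sd additive measurement noise, counts.
#' @return A list with one element per frequency: `true_hz`,
#'   `analogue` (data.frame `t` ms, `speed`, `turn`; 250 Hz),
#'   `digital` (a 50 Hz [joystick_log]).
#' @export
simulate_artificial_tremors <- function(frequencies = seq(3, 9, length.out = 16),
                                        seed = 1, duration_s = 10,
                                        amp = 30, noise_sd = 0.5) {
  stopifnot(all(frequencies > 0), all(frequencies < 25))
  set.seed(seed)
  hi_rate <- 250
  dec <- hi_rate / 50
  t_s <- seq(0, duration_s - 1 / hi_rate, by = 1 / hi_rate)
  lapply(frequencies, function(f) {
    phase <- stats::runif(1, 0, 2 * pi)
    y <- amp * sin(2 * pi * f * t_s + phase) +
      stats::rnorm(length(t_s), 0, noise_sd)
    x <- 0.4 * amp * cos(2 * pi * f * t_s + phase) +
      stats::rnorm(length(t_s), 0, noise_sd)
    idx <- seq(1, length(t_s), by = dec)
    list(
      true_hz = f,
      analogue = data.frame(t = round(t_s * 1000), speed = y, turn = x),
      digital = joystick_log(t = round(t_s[idx] * 1000), speed = y[idx],
                             turn = x[idx], sample_rate_hz = 50,
                             meta = list(synthetic = TRUE, true_hz = f))
    )
  })
}

#' Driving course specification
#'
#' Schematic confined-space course: waypoints to visit in order, wall
#' segments and circular posts as obstacles, and platform limits. The default
#' is a 2 m wide corridor with two offset posts to steer around.
#'
#' @param waypoints matrix/data.frame of x, y waypoint coordinates, metres.
#' @param walls data.frame of wall segments (`x1`, `y1`, `x2`, `y2`), metres.
#' @param posts data.frame of circular posts (`x`, `y`, `r`), metres.
#' @param v_max platform forward speed limit, m/s.
#' @param sensor_max ultrasound range ceiling, metres.
#' @return A list of class `course_spec`.
#' @export
course_spec <- function(waypoints = cbind(x = c(2, 4, 6, 8, 10), y = 0),
                        walls = data.frame(x1 = c(0, 0), y1 = c(-1, 1),
                                           x2 = c(11, 11), y2 = c(-1, 1)),
                        posts = data.frame(x = c(5, 8), y = c(0.55, -0.55),
                                           r = 0.1),
                        v_max = 0.8, sensor_max = 5) {
  structure(list(waypoints = as.matrix(waypoints), walls = walls,
                 posts = posts, v_max = v_max, sensor_max = sensor_max),
            class = "course_spec")
}

#' Integrate a platform pose from a joystick trace
#'
#' Maps joystick counts to body velocities (`v = speed/127 * v_max`,
#' `omega = turn/127 * 2 v_max / W`, positive turn = clockwise) and
#' integrates the differential-drive pose at the sample rate.
#'
#' @param samples data.frame `t` (ms), `speed`, `turn`.
#' @param wheel_base_w wheel separation, metres.
#' @param v_max forward speed at full throw, m/s.
#' @return data.frame `t`, `x`, `y` (metres, world frame), `theta` (radians,
#'   anticlockwise from +x).
#' @export
integrate_pose <- function(samples, wheel_base_w = 0.5, v_max = 0.8) {
  n <- nrow(samples)
  x <- y <- theta <- numeric(n)
  dt <- c(diff(samples$t), 0) / 1000
  for (i in seq_len(n - 1L)) {
    v <- samples$speed[i] / 127 * v_max
    om <- -samples$turn[i] / 127 * (2 * v_max / wheel_base_w)  # CW command -> CCW rate
    x[i + 1L] <- x[i] + v * cos(theta[i]) * dt[i]
    y[i + 1L] <- y[i] + v * sin(theta[i]) * dt[i]
    theta[i + 1L] <- theta[i] + om * dt[i]
  }
  data.frame(t = samples$t, x = x, y = y, theta = theta)
}

# distance from point (px,py) along world direction (dx,dy) to course
# obstacles; Inf when nothing is hit
ray_cast <- function(course, px, py, dx, dy) {
  best <- Inf
  w <- course$walls
  if (!is.null(w) && nrow(w)) {
    for (i in seq_len(nrow(w))) {
      ex <- w$x2[i] - w$x1[i]; ey <- w$y2[i] - w$y1[i]
      den <- dx * ey - dy * ex
      if (abs(den) < 1e-12) next
      s <- ((w$x1[i] - px) * ey - (w$y1[i] - py) * ex) / den
      u <- if (abs(ex) > abs(ey)) (px + s * dx - w$x1[i]) / ex
           else (py + s * dy - w$y1[i]) / ey
      if (s > 0 && u >= 0 && u <= 1 && s < best) best <- s
    }
  }
  p <- course$posts
  if (!is.null(p) && nrow(p)) {
    for (i in seq_len(nrow(p))) {
      ox <- p$x[i] - px; oy <- p$y[i] - py
      proj <- ox * dx + oy * dy
      if (proj <= 0) next
      perp2 <- ox^2 + oy^2 - proj^2
      if (perp2 > p$r[i]^2) next
      s <- proj - sqrt(p$r[i]^2 - perp2)
      if (s > 0 && s < best) best <- s
    }
  }
  best
}

scan_at_pose <- function(course, x, y, theta, sector_angles) {
  vapply(sector_angles, function(b) {
    ang <- theta - b * pi / 180  # clockwise body bearing -> world angle
    min(ray_cast(course, x, y, cos(ang), sin(ang)), course$sensor_max)
  }, numeric(1))
}

#' Simulate a run around a driving course
#'
#' A pursuit-style driver model steers the platform through the course
#' waypoints: the joystick intent points at the next waypoint (turn
#' proportional to heading error, speed backed off in sharp turns), rendered
#' through the archetype's tremor and jitter, the pose integrated with the
#' differential-drive kinematics, and per-sector ultrasound ranges ray-cast
#' against the course obstacles at every sample. With a [dlaff_config] the
#' collision-damping layer corrects each command before it drives the
#' platform, and the corrected trace and per-wheel multipliers are returned
#' alongside the raw input.
#'
#' @param archetype a [user_archetype].
#' @param course a [course_spec].
#' @param dlaff_cfg optional [dlaff_config]; `NULL` runs unassisted.
#' @param sample_rate_hz sample rate, Hz.
#' @param seed RNG seed.
#' @param max_duration_s simulation cap; failing to reach the waypoints in
#'   this time is an error (unreachable course).
#' @param sector_angles scan sector bearings, degrees body frame.
#' @return A [joystick_log] with scans; attributes `pose` (data.frame),
#'   and, when damped, `corrected` (data.frame) and `multipliers`.
#' @export
simulate_course_run <- function(archetype, course = course_spec(),
                                dlaff_cfg = NULL, sample_rate_hz = 50,
                                seed = NULL, max_duration_s = 300,
                                sector_angles = seq(0, 315, by = 45)) {
  if (!is.null(seed)) set.seed(seed)
  rate <- sample_rate_hz
  dt <- 1 / rate
  n_max <- round(max_duration_s * rate)
  wp <- course$waypoints
  wp_i <- 1L
  x <- y <- theta <- 0
  jitter_sd <- archetype$smooth_noise / rate
  spd <- trn <- numeric(n_max)
  cspd <- ctrn <- numeric(n_max)
  ml <- mr <- rep(1, n_max)
  px <- py <- pth <- numeric(n_max)
  scans <- matrix(NA_real_, n_max, length(sector_angles))
  i <- 0L
  while (wp_i <= nrow(wp) && i < n_max) {
    i <- i + 1L
    tx <- wp[wp_i, 1] - x; ty <- wp[wp_i, 2] - y
    if (sqrt(tx^2 + ty^2) < 0.4) {
      wp_i <- wp_i + 1L
      if (wp_i > nrow(wp)) { i <- i - 1L; break }
      tx <- wp[wp_i, 1] - x; ty <- wp[wp_i, 2] - y
    }
    err <- atan2(ty, tx) - theta
    err <- atan2(sin(err), cos(err))
    turn_cmd <- max(-127, min(127, -err / (pi / 2) * 127 * 1.5))
    speed_cmd <- max(15, 110 * max(0, cos(err)))
    t_now <- (i - 1) * dt
    if (archetype$tremor_hz > 0 && archetype$tremor_amp > 0) {
      speed_cmd <- speed_cmd +
        archetype$tremor_amp * sin(2 * pi * archetype$tremor_hz * t_now)
      turn_cmd <- turn_cmd +
        0.5 * archetype$tremor_amp * cos(2 * pi * archetype$tremor_hz * t_now)
    }
    if (jitter_sd > 0) {
      speed_cmd <- speed_cmd + stats::rnorm(1, 0, jitter_sd)
      turn_cmd <- turn_cmd + stats::rnorm(1, 0, jitter_sd)
    }
    speed_cmd <- max(-128, min(127, speed_cmd))
    turn_cmd <- max(-128, min(127, turn_cmd))
    sc <- scan_at_pose(course, x, y, theta, sector_angles)
    scans[i, ] <- sc
    spd[i] <- speed_cmd; trn[i] <- turn_cmd
    if (!is.null(dlaff_cfg)) {
      d <- apply_damping(speed_cmd, turn_cmd, sc, sector_angles, dlaff_cfg)
      cspd[i] <- d$speed; ctrn[i] <- d$turn
      ml[i] <- d$left_multiplier; mr[i] <- d$right_multiplier
      drive_s <- d$speed; drive_t <- d$turn
    } else {
      cspd[i] <- speed_cmd; ctrn[i] <- turn_cmd
      drive_s <- speed_cmd; drive_t <- turn_cmd
    }
    v <- drive_s / 127 * course$v_max
    om <- -drive_t / 127 * (2 * course$v_max / 0.5)
    px[i] <- x; py[i] <- y; pth[i] <- theta
    x <- x + v * cos(theta) * dt
    y <- y + v * sin(theta) * dt
    theta <- theta + om * dt
  }
  if (wp_i <= nrow(wp)) stop("simulation error: waypoints unreachable within the time cap")
  idx <- seq_len(i)
  t_ms <- round((idx - 1) * dt * 1000)
  log <- joystick_log(
    t = t_ms, speed = spd[idx], turn = trn[idx], sample_rate_hz = rate,
    scans = proximity_scans(t = t_ms, ranges = scans[idx, , drop = FALSE],
                            sector_angles = sector_angles),
    meta = list(synthetic = TRUE, course = TRUE)
  )
  attr(log, "pose") <- data.frame(t = t_ms, x = px[idx], y = py[idx],
                                  theta = pth[idx])
  if (!is.null(dlaff_cfg)) {
    attr(log, "corrected") <- data.frame(t = t_ms, speed = cspd[idx],
                                         turn = ctrn[idx])
    attr(log, "multipliers") <- data.frame(left = ml[idx], right = mr[idx])
  }
  log
}

#' Generate a labelled synthetic cohort of feature vectors
#'
#' Builds `n_users` distinct archetypes (parameter offsets from a shared base,
#' scaled by `separation`; 0 makes every user identical), simulates
#' `runs_per_user` traces per user per day, and extracts the 15-feature
#' long-term vector from each. With `drift` each archetype's severity
#' parameters change multiplicatively day to day, so day labels become
#' learnable; without it days differ only by simulation noise.
#'
#' @param n_users number of users (>= 2).
#' @param runs_per_user runs per user per day.
#' @param drift inject day-to-day drift?
#' @param n_days number of days (1 unless drifting).
#' @param separation archetype separation scaling (>= 0).
#' @param seed RNG seed; the dataset is deterministic given all arguments.
#' @param duration_s trace length per run, seconds.
#' @return data.frame: `user`, `day`, `run`, then the 15 feature columns.
#' @export
make_cohort <- function(n_users, runs_per_user, drift = FALSE,
                        n_days = if (drift) 3 else 1, separation = 1,
                        seed = 1, duration_s = 60) {
  stopifnot(n_users >= 2, runs_per_user >= 1, separation >= 0)
  set.seed(seed)
  base <- default_ellipse_target()
  users <- lapply(seq_len(n_users), function(u) {
    ell <- base
    ell$A <- pmax(4, ell$A * (1 + separation * stats::runif(4, -0.5, 0.5)))
    ell$B <- pmax(8, ell$B * (1 + separation * stats::runif(4, -0.5, 0.5)))
    ell$cx <- ell$cx + sign(ell$cx) * separation * stats::runif(4, -8, 8)
    ell$cy <- ell$cy + sign(ell$cy) * separation * stats::runif(4, -10, 10)
    # keep the sampling boxes inside their quadrants and the count range
    ell$A <- pmin(ell$A, abs(ell$cx) - 3)
    ell$B <- pmin(ell$B, abs(ell$cy) - 3)
    user_archetype(
      ellipse_target = ell,
      tremor_hz = if (stats::runif(1) < 0.4 * min(separation, 1)) stats::runif(1, 4, 11) else 0,
      tremor_amp = separation * stats::runif(1, 3, 12),
      smooth_noise = 40 + separation * stats::runif(1, 0, 120),
      stop_drive_ratio = exp(log(1.5) + separation * stats::runif(1, -0.5, 0.5)),
      drift_per_day = if (drift) stats::runif(1, 1.25, 1.6) else 1
    )
  })
  run_seeds <- sample.int(2^30, n_users * n_days * runs_per_user)
  rows <- list()
  k <- 0L
  for (u in seq_len(n_users)) {
    for (d in seq_len(n_days)) {
      for (r in seq_len(runs_per_user)) {
        k <- k + 1L
        log <- simulate_trace(users[[u]], duration_s, seed = run_seeds[k],
                              day = d)
        fv <- build_feature_vector(log, variant = "long_term")
        rows[[k]] <- cbind(data.frame(user = paste0("U", u), day = d, run = r),
                          as.data.frame(as.list(unclass(fv))))
      }
    }
  }
  do.call(rbind, rows)
}
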