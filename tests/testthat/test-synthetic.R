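test_that("simulated traces respect the telemetry invariants", {
  for (seed in c(61, 62)) {
    log <- simulate_trace(user_archetype(tremor_hz = 7, tremor_amp = 25,
                                         smooth_noise = 150),
                          duration_s = 30, seed = seed)
    s <- log$samples
    expect_true(all(diff(s$t) > 0))
    expect_true(all(s$speed >= -128 & s$speed <= 127))
    expect_true(all(s$turn >= -128 & s$turn <= 127))
  }
  expect_error(simulate_trace(user_archetype(), duration_s = 5), "at least 10")
})

test_that("injected generative parameters are recovered by the extractors", {
  # tremor frequency, measured in the tremor band
  cfg <- spectrum_config(min_freq_hz = 4, max_freq_hz = 11)
  a <- user_archetype(tremor_hz = 6, tremor_amp = 20)
  log <- simulate_trace(a, 60, seed = 11)
  r <- fft_dominant_frequency(log$samples$speed, 50, cfg)
  expect_lte(abs(r$f_fft_hz - 6), r$bin_width_hz)

  # ellipse semi-axes within 10%, with over 5000 driving samples
  ell <- default_ellipse_target()
  ell$B[ell$quadrant == "forward_right"] <- 80
  ell$cy[ell$quadrant == "forward_right"] <- 85
  log2 <- simulate_trace(user_archetype(ellipse_target = ell), 240, seed = 12)
  e2 <- position_ellipse(log2$samples)
  expect_equal(e2$B[e2$quadrant == "forward_right"], 80, tolerance = 0.1)
  expect_equal(e2$A[e2$quadrant == "forward_left"], 15, tolerance = 0.1)

  # stop/drive ratio within 10%
  tm <- timing(simulate_trace(user_archetype(stop_drive_ratio = 1.5), 300,
                              seed = 13))
  expect_equal(tm$ratio, 1.5, tolerance = 0.1)

  # jitter-free constant sweep: smoothness equals the sweep rate
  sweep <- data.frame(t = seq(0, 1980, by = 20), speed = seq(1, 100), turn = 0)
  expect_equal(smoothness_score(sweep)$score, 50)
})

test_that("artificial tremor fixtures pair a 250 Hz and a decimated 50 Hz path", {
  fx <- simulate_artificial_tremors(seed = 2)
  expect_length(fx, 16)
  for (z in fx[c(1, 8, 16)]) {
    dec <- z$analogue$speed[seq(1, nrow(z$analogue), by = 5)]
    expect_equal(z$digital$samples$speed, dec)
  }
  # cross-method agreement on every fixture
  for (z in fx) {
    f_dig <- fft_dominant_frequency(z$digital$samples$speed, 50)$f_fft_hz
    f_ana <- fft_dominant_frequency(z$analogue$speed, 250)$f_fft_hz
    expect_lte(abs(f_dig - f_ana), 1)
    expect_lte(abs(f_dig - z$true_hz), 0.2)
  }
  # peak counting recovers a 7 Hz fixture
  fx7 <- simulate_artificial_tremors(frequencies = 7, seed = 3)[[1]]
  expect_lte(abs(peak_count_frequency(fx7$digital$samples$speed, 50) - 7), 1)
})

test_that("course runs ray-cast ranges and integrate the platform pose", {
  open <- course_spec(walls = data.frame(x1 = numeric(0), y1 = numeric(0),
                                         x2 = numeric(0), y2 = numeric(0)),
                      posts = data.frame(x = numeric(0), y = numeric(0),
                                         r = numeric(0)))
  log <- simulate_course_run(user_archetype(smooth_noise = 10), open, seed = 71)
  expect_true(all(log$scans$ranges == open$sensor_max))

  # no obstacles in range: DLAFF never intervenes, proximity bias is zero
  log_d <- simulate_course_run(user_archetype(smooth_noise = 10), open,
                               dlaff_cfg = dlaff_config(), seed = 71)
  expect_true(all(attr(log_d, "multipliers") == 1))
  bias <- proximity_bias_feature(log_d$samples[c("t", "speed", "turn")],
                                 attr(log_d, "corrected"))
  expect_true(all(bias == 0))

  # spin-in-place: rotation budget is 4x the forward budget at W = 0.5 m
  spin <- data.frame(t = seq(0, 2000, by = 20), speed = 0, turn = 127)
  fwd <- data.frame(t = seq(0, 2000, by = 20), speed = 127, turn = 0)
  pose_s <- integrate_pose(spin, wheel_base_w = 0.5, v_max = 1)
  pose_f <- integrate_pose(fwd, wheel_base_w = 0.5, v_max = 1)
  rot_rate <- abs(pose_s$theta[101] - pose_s$theta[1]) / 2
  fwd_rate <- (pose_f$x[101] - pose_f$x[1]) / 2
  expect_equal(rot_rate / fwd_rate, 4, tolerance = 1e-6)
})

test_that("a corridor narrowing inside the inner ellipse floors the damping", {
  cfg <- dlaff_config()
  sect <- seq(0, 315, by = 45)
  # converging walls: half-width shrinks from 1 m to 0.25 m over 10 m
  half_w <- function(x) 1 - 0.075 * x
  # independent range oracle for a pose on the centreline facing +x:
  # distance to the wall lines along each sector bearing
  ranges_at <- function(x) {
    vapply(sect, function(b) {
      th <- -b * pi / 180  # world angle of the ray (pose theta = 0)
      dx <- cos(th); dy <- sin(th)
      best <- 5
      for (side in c(1, -1)) {
        # wall: y = side * (1 - 0.075 x)  ->  solve along the ray
        den <- dy + side * 0.075 * dx
        if (abs(den) < 1e-12) next
        s <- (side * (1 - 0.075 * x)) / den
        if (s > 0 && s < best) best <- s
      }
      best
    }, numeric(1))
  }
  floors_hit <- FALSE
  contact <- FALSE
  for (x in seq(0, 10, by = 0.5)) {
    rg <- ranges_at(x)
    if (half_w(x) <= 0) { contact <- TRUE; break }
    r <- apply_damping(100, 0, rg, sect, cfg)
    if (r$left_multiplier == cfg$floor && r$right_multiplier == cfg$floor) {
      floors_hit <- TRUE
      break
    }
  }
  expect_true(floors_hit)   # damping saturates...
  expect_false(contact)     # ...strictly before the walls close on the platform
})

test_that("cohorts have the requested shape and are deterministic under a seed", {
  co <- make_cohort(n_users = 14, runs_per_user = 4, seed = 1, duration_s = 20)
  expect_equal(nrow(co), 56)
  expect_equal(length(unique(co$user)), 14)
  expect_equal(ncol(co), 3 + 15)
  co2 <- make_cohort(n_users = 14, runs_per_user = 4, seed = 1, duration_s = 20)
  expect_identical(co, co2)
})
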