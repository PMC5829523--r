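test_that("radial distances reduce to radii for circles and obey the conic law", {
  cfg <- dlaff_config(inner = dlaff_ellipse(0.7, 0), outer = dlaff_ellipse(1.8, 0))
  for (b in seq(0, 350, by = 37)) {
    d <- radial_distances(cfg, b)
    expect_equal(d$p, 0.7)
    expect_equal(d$R, 1.8)
  }

  # displaced focus: the intersection point must satisfy |P-O| + |P-F| = 2a
  ell <- dlaff_ellipse(semi_major = 1.2, focus_f = 0.8)
  cfg2 <- dlaff_config(inner = dlaff_ellipse(0.5, 0.3), outer = ell)
  for (b in seq(0, 359, by = 17)) {
    t <- radial_distances(cfg2, b)$R
    th <- b * pi / 180
    p_xy <- t * c(cos(th), sin(th))
    expect_equal(t + sqrt(sum((p_xy - c(0.8, 0))^2)), 2 * 1.2)
  }
  # bearing 0 closed form: focal chord along the major axis
  expect_equal(radial_distances(cfg2, 0)$R,
               (4 * 1.2^2 - 0.8^2) / (4 * 1.2 - 2 * 0.8))
})

test_that("lateral extension widens the sides only", {
  base <- dlaff_ellipse(1.5, 0.5)
  wide <- dlaff_ellipse(1.5, 0.5, lateral_extension = 0.4)
  cfg_b <- dlaff_config(inner = dlaff_ellipse(0.5, 0.2), outer = base)
  cfg_w <- dlaff_config(inner = dlaff_ellipse(0.5, 0.2), outer = wide)
  expect_equal(radial_distances(cfg_w, 0)$R, radial_distances(cfg_b, 0)$R)
  expect_equal(radial_distances(cfg_w, 90)$R,
               radial_distances(cfg_b, 90)$R + 0.4)
  expect_equal(radial_distances(cfg_w, 270)$R,
               radial_distances(cfg_b, 270)$R + 0.4)
})

test_that("configuration invariants are enforced", {
  expect_error(dlaff_ellipse(0.3, 0.8), "degenerate")
  expect_error(dlaff_config(inner = dlaff_ellipse(1.5, 0),
                            outer = dlaff_ellipse(1.0, 0)), "contain")
  expect_error(dlaff_config(floor = 1.5), "floor")
  expect_error(damping_factor(1, p = 2, R = 1), "greater")
})

test_that("damping multiplier spans [floor, 1], monotonically in distance", {
  p <- 0.8; R <- 2; k <- 0.3
  expect_equal(damping_factor(R, p, R, k), 1)
  expect_equal(damping_factor(5, p, R, k), 1)
  expect_equal(damping_factor(p, p, R, k), 0.01)
  expect_equal(damping_factor(0.2, p, R, k), 0.01)

  # the raw exponential curve at one k of penetration is 1 - 1/e
  m <- damping_factor(p + k, p, R, k)
  raw_range <- 1 - exp(-(R - p) / k)
  expect_equal((m - 0.01) / (1 - 0.01) * raw_range, 1 - exp(-1))

  d <- seq(0, 3, by = 0.01)
  f <- damping_factor(d, p, R, k)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0.01 & f <= 1))
  # continuity at the ellipse boundaries
  eps <- 1e-9
  expect_equal(damping_factor(p + eps, p, R, k), 0.01, tolerance = 1e-6)
  expect_equal(damping_factor(R - eps, p, R, k), 1, tolerance = 1e-6)

  # smaller k = steeper curve: less damping applied at mid-gap
  mid <- (p + R) / 2
  ks <- c(0.6, 0.3, 0.15, 0.075)
  mids <- vapply(ks, function(kk) damping_factor(mid, p, R, kk), numeric(1))
  expect_true(all(diff(mids) > 0))
})

test_that("differential-drive kinematics and its inverse are exact", {
  expect_equal(kinematics(1, 1, 0.5), list(v = 1, omega = 0))
  expect_equal(kinematics(0.5, -0.5, 0.5), list(v = 0, omega = 2))
  expect_error(kinematics(1, 1, 0), "separation")

  # unit wheel budget: spin rate over forward rate = 2 / W
  expect_equal(kinematics(1, -1, 0.5)$omega / kinematics(1, 1, 0.5)$v, 4)
  expect_equal(kinematics(1, -1, 2)$omega / kinematics(1, 1, 2)$v, 1)

  set.seed(19)
  for (i in 1:20) {
    v <- stats::runif(1, -2, 2); om <- stats::runif(1, -4, 4)
    w <- stats::runif(1, 0.3, 1)
    wh <- inverse_kinematics(v, om, w)
    back <- kinematics(wh$v_right, wh$v_left, w)
    expect_equal(back$v, v)
    expect_equal(back$omega, om)
  }
})

test_that("damping applies the cross rule and never amplifies a wheel", {
  cfg <- dlaff_config()
  sect <- seq(0, 315, by = 45)
  far <- rep(5, 8)

  # everything beyond the outer ellipse: pass-through
  r <- apply_damping(100, 20, far, sect, cfg)
  expect_equal(c(r$speed, r$turn), c(100, 20))

  # symmetric close obstacles, straight push: slower but straight
  sym <- far
  sym[sect == 45] <- 1.2
  sym[sect == 315] <- 1.2
  r2 <- apply_damping(100, 0, sym, sect, cfg)
  expect_lt(r2$speed, 100)
  expect_equal(r2$turn, 0)

  # single forward-right obstacle at mid-gap: manual wheel-mix oracle
  one <- far
  one[sect == 45] <- 1.5
  pr <- radial_distances(cfg, 45)
  m <- damping_factor(1.5, pr$p, pr$R, cfg$k, cfg$floor)
  r3 <- apply_damping(100, 0, one, sect, cfg)
  # wheels from straight push are (100, 100); left wheel damped by m
  expect_equal(r3$left_multiplier, m)
  expect_equal(r3$speed, (100 + 100 * m) / 2)
  expect_equal(r3$turn, (100 - 100 * m) / 2)
  expect_gt(r3$turn, 0)  # command yaws right, away from its own track

  # wheel signals keep their sign and never grow
  set.seed(23)
  for (i in 1:30) {
    sp <- stats::runif(1, -120, 120); tn <- stats::runif(1, -120, 120)
    ranges <- stats::runif(8, 0.2, 5)
    rr <- apply_damping(sp, tn, ranges, sect, cfg)
    w_in <- list(r = sp + tn, l = sp - tn)
    w_out <- list(r = rr$speed + rr$turn, l = rr$speed - rr$turn)
    expect_lte(abs(w_out$r), abs(w_in$r) + 1e-12)
    expect_lte(abs(w_out$l), abs(w_in$l) + 1e-12)
    expect_true(all(sign(c(w_out$r, w_out$l)) == sign(c(w_in$r, w_in$l)) |
                      c(w_out$r, w_out$l) == 0))
    expect_true(all(c(rr$left_multiplier, rr$right_multiplier) >= cfg$floor))
  }
})

test_that("damping is left/right mirror symmetric", {
  cfg <- dlaff_config()
  sect <- seq(0, 315, by = 45)
  set.seed(29)
  for (i in 1:20) {
    ranges <- stats::runif(8, 0.3, 5)
    sp <- stats::runif(1, -120, 120); tn <- stats::runif(1, -120, 120)
    r <- apply_damping(sp, tn, ranges, sect, cfg)
    # mirror: bearing b -> -b, turn -> -turn
    mirror_sect <- (360 - sect) %% 360
    rm <- apply_damping(sp, -tn, ranges, mirror_sect, cfg)
    expect_equal(rm$speed, r$speed)
    expect_equal(rm$turn, -r$turn)
    expect_equal(rm$left_multiplier, r$right_multiplier)
    expect_equal(rm$right_multiplier, r$left_multiplier)
  }
})

test_that("proximity bias isolates the quadrant where correction happened", {
  t_ms <- seq(0, 1980, by = 20)
  user <- data.frame(t = t_ms,
                     speed = rep(c(60, -60), each = 50),
                     turn = rep(c(30, 30), each = 50))
  expect_true(all(proximity_bias_feature(user, user) == 0))

  corrected <- user
  idx <- user$speed > 0  # forward-right samples
  corrected$speed[idx] <- corrected$speed[idx] - 8
  b <- proximity_bias_feature(user, corrected, window_s = 0.2)
  expect_equal(unname(b["forward_right"]), 8, tolerance = 0.15)
  expect_equal(unname(b["rear_right"]), 0, tolerance = 0.15)
  expect_equal(unname(b["forward_left"]), 0)
  expect_error(proximity_bias_feature(user, corrected[-1, ]), "misaligned")
})
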