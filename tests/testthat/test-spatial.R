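test_that("quadrant assignment follows the boundary rules", {
  expect_equal(assign_quadrant(50, -30), "forward_left")
  expect_equal(assign_quadrant(0, 0), NA_character_)
  expect_equal(assign_quadrant(-10, 5), "rear_right")
  expect_equal(assign_quadrant(0, 30), "forward_right")  # pure turn -> forward
  expect_equal(assign_quadrant(10, 0), "forward_right")  # turn 0 -> right

  # enumeration oracle over uniform random samples
  set.seed(3)
  speed <- sample(-128:127, 2000, replace = TRUE)
  turn <- sample(-128:127, 2000, replace = TRUE)
  got <- assign_quadrant(speed, turn, deadband = 2)
  want <- vapply(seq_along(speed), function(i) {
    if (max(abs(speed[i]), abs(turn[i])) <= 2) return(NA_character_)
    fr <- if (speed[i] > 0 || speed[i] == 0) "forward" else "rear"
    lr <- if (turn[i] < 0) "left" else "right"
    paste(fr, lr, sep = "_")
  }, character(1))
  expect_equal(got, want)
})

test_that("position ellipse computes IQR semi-axes and quartile centres", {
  s <- data.frame(speed = rep(60, 11), turn = 10:20)
  e <- position_ellipse(s)
  fr <- e[e$quadrant == "forward_right", ]
  expect_equal(fr$A, 5)       # IQR of 10..20 with interpolated quartiles
  expect_equal(fr$B, 0)
  expect_equal(fr$cx, 15)
  expect_equal(fr$cy, 60)
  expect_true(all(e$empty[e$quadrant != "forward_right"]))

  same <- data.frame(speed = rep(40, 6), turn = rep(-25, 6))
  e2 <- position_ellipse(same)
  fl <- e2[e2$quadrant == "forward_left", ]
  expect_equal(c(fl$A, fl$B), c(0, 0))
  expect_equal(c(fl$cx, fl$cy), c(-25, 40))

  few <- data.frame(speed = c(50, 60, 70), turn = c(10, 12, 14))
  expect_true(position_ellipse(few)$empty[2])
})

test_that("position ellipse is invariant to sample order and interleaving", {
  set.seed(11)
  s <- data.frame(speed = sample(-128:127, 500, replace = TRUE),
                  turn = sample(-128:127, 500, replace = TRUE))
  base <- position_ellipse(s)
  shuf <- position_ellipse(s[sample(nrow(s)), ])
  expect_equal(shuf, base)
  # duplicating every sample leaves the quartile geometry unchanged
  dup <- position_ellipse(rbind(s, s))
  expect_equal(dup[c("A", "B", "cx", "cy")], base[c("A", "B", "cx", "cy")],
               tolerance = 0.02)
})

test_that("velocity-vector bias reports ordered quartiles per quadrant", {
  still <- data.frame(t = seq(0, 980, by = 20), speed = 30, turn = 10)
  v <- velocity_vector_bias(still)
  expect_true(all(v$median == 0))

  # constant-rate sweep inside forward-right: median = rate (x calibration)
  sw <- data.frame(t = seq(0, 980, by = 20),
                   speed = seq(20, 69, by = 1), turn = 15)
  r_counts <- 1 / 0.02
  v2 <- velocity_vector_bias(sw, counts_to_mm = 0.2)
  expect_equal(v2[v2$quadrant == "forward_right", "median"], r_counts * 0.2)

  set.seed(13)
  s <- data.frame(t = seq(0, 1980, by = 20),
                  speed = stats::runif(100, -128, 127),
                  turn = stats::runif(100, -128, 127))
  v3 <- velocity_vector_bias(s)
  expect_true(all(v3$q1 <= v3$median & v3$median <= v3$q3))
})

test_that("remapping is the standard linear interval map", {
  ident <- remap_spec(0, 128, 0, 128)
  expect_equal(remap_value(c(-5, 0, 64, 127), ident), c(-5, 0, 64, 127))
  half <- remap_spec(0, 128, 0, 32)
  expect_equal(remap_value(64, half), 16)
  expect_error(remap_spec(0, 0, 0, 10), "nonzero")

  set.seed(7)
  spec <- remap_spec(-30, 90, 10, 55)
  x <- stats::runif(1000, -50, 80)
  expect_equal(remap_value(remap_value(x, spec), invert_remap(spec)), x)
  # affine: preserves midpoints
  a <- stats::runif(50, -50, 80)
  b <- stats::runif(50, -50, 80)
  expect_equal(remap_value((a + b) / 2, spec),
               (remap_value(a, spec) + remap_value(b, spec)) / 2)
  # clamping pins outputs to the target interval
  cl <- remap_spec(0, 10, 0, 10, clamp = TRUE)
  expect_equal(remap_value(c(-5, 15), cl), c(0, 10))
})

test_that("derived remaps recover the target ellipse from user samples", {
  set.seed(17)
  box_samples <- function(cx, a, cy, b, n = 1200) {
    data.frame(speed = stats::runif(n, cy - b, cy + b),
               turn = stats::runif(n, cx - a, cx + a))
  }
  user_s <- rbind(box_samples(20, 8, 40, 20), box_samples(-20, 8, 40, 20),
                  box_samples(20, 8, -35, 15), box_samples(-20, 8, -35, 15))
  target_s <- rbind(box_samples(30, 14, 60, 35), box_samples(-30, 14, 60, 35),
                    box_samples(25, 12, -55, 25), box_samples(-25, 12, -55, 25))
  user <- position_ellipse(user_s)
  target <- position_ellipse(target_s)
  specs <- derive_remap_from_ellipse(user, target)
  re <- position_ellipse(apply_remap(user_s, specs))
  expect_equal(re$A, target$A, tolerance = 0.05)
  expect_equal(re$B, target$B, tolerance = 0.05)

  # user == target -> identity maps
  specs_id <- derive_remap_from_ellipse(target, target)
  same <- apply_remap(target_s, specs_id)
  expect_equal(same$speed, target_s$speed, tolerance = 1e-10)
  expect_equal(same$turn, target_s$turn, tolerance = 1e-10)

  # a doubling spec doubles the speed-axis spread
  u1 <- user
  u1[u1$quadrant == "forward_right", c("B", "cy")] <- c(40, 30)
  t1 <- target
  t1[t1$quadrant == "forward_right", c("B", "cy")] <- c(80, 60)
  sp <- derive_remap_from_ellipse(u1, t1)$forward_right$y
  expect_equal(sp$range_out / sp$range_in, 2)
})

test_that("a compressed-throw user is restored to full range by remapping", {
  # 50% deflection archetype: all axes at half the intended throw
  full <- default_ellipse_target()
  half <- full
  half[c("A", "B", "cx", "cy")] <- full[c("A", "B", "cx", "cy")] / 2
  log <- simulate_trace(user_archetype(ellipse_target = half, smooth_noise = 0),
                        duration_s = 240, seed = 31)
  user <- position_ellipse(log$samples)
  target_samples <- simulate_trace(user_archetype(ellipse_target = full,
                                                  smooth_noise = 0),
                                   duration_s = 240, seed = 32)$samples
  target <- position_ellipse(target_samples)
  remapped <- apply_remap(log$samples, derive_remap_from_ellipse(user, target))
  re <- position_ellipse(remapped)
  expect_equal(re$B, target$B, tolerance = 0.1)
  expect_equal(re$A, target$A, tolerance = 0.1)
})
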