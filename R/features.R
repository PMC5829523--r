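fixed_course_fields <- c(
  "fft_hz", "smoothness",
  "fla", "flb", "fra", "frb", "rla", "rlb", "rra", "rrb",
  "vel_fl", "vel_fr", "vel_rl", "vel_rr",
  "obst_fl", "obst_fr", "obst_rl", "obst_rr",
  "drive_ratio", "total_time_s"
)
long_term_fields <- setdiff(fixed_course_fields,
                            c("obst_fl", "obst_fr", "obst_rl", "obst_rr",
                              "total_time_s"))

#' Assemble a driving feature vector from a telemetry log
#'
#' Runs the whole feature pipeline on one log and assembles the result in the
#' documented field order. Two variants exist: the 20-feature
#' `"fixed_course"` vector (tremor frequency, smoothness, the eight position
#' bias ellipse semi-axes, four per-quadrant velocity-vector medians, four
#' obstacle-proximity biases, motion/stationary ratio and total time) and
#' the 15-feature `"long_term"` vector, which drops the obstacle biases and
#' total time for monitoring in an uninstrumented daily environment.
#'
#' Ellipse fields follow the `fra`/`flb` abbreviation scheme: quadrant
#' (forward/rear, right/left) then semi-axis (`a` = turn spread, `b` = speed
#' spread). Empty quadrants contribute 0 (not NA): an unvisited quadrant is
#' a real property of the run, and classifiers need complete vectors.
#'
#' @param log a [joystick_log]; the fixed-course variant requires `log$scans`.
#' @param variant `"fixed_course"` (20 features) or `"long_term"` (15).
#' @param dlaff_cfg a [dlaff_config] used to compute the corrected trace for
#'   the obstacle-bias features (fixed-course variant only).
#' @param deadband motion/quadrant deadband, counts.
#' @param counts_to_mm velocity-bias throw calibration, mm per count.
#' @param smoothness_scale calibration multiplier for the smoothness score.
#' @return A named numeric vector of class `feature_vector` with attribute
#'   `variant`.
#' @export
build_feature_vector <- function(log, variant = c("fixed_course", "long_term"),
                                 dlaff_cfg = dlaff_config(), deadband = 2,
                                 counts_to_mm = 0.2, smoothness_scale = 1) {
  variant <- match.arg(variant)
  s <- log$samples
  rate <- log$sample_rate_hz
  fft <- fft_dominant_frequency(s$speed, rate)
  sm <- smoothness_score(s, scale_factor = smoothness_scale)
  ell <- position_ellipse(s, deadband)
  vel <- velocity_vector_bias(s, counts_to_mm, deadband)
  tm <- timing(s, deadband, rate)
  ell_val <- function(lab, axis) {
    v <- ell[ell$quadrant == lab, axis]
    if (is.na(v)) 0 else v
  }
  vel_val <- function(lab) vel[vel$quadrant == lab, "median"]
  out <- c(
    fft_hz = fft$f_fft_hz,
    smoothness = sm$score,
    fla = ell_val("forward_left", "A"), flb = ell_val("forward_left", "B"),
    fra = ell_val("forward_right", "A"), frb = ell_val("forward_right", "B"),
    rla = ell_val("rear_left", "A"), rlb = ell_val("rear_left", "B"),
    rra = ell_val("rear_right", "A"), rrb = ell_val("rear_right", "B"),
    vel_fl = vel_val("forward_left"), vel_fr = vel_val("forward_right"),
    vel_rl = vel_val("rear_left"), vel_rr = vel_val("rear_right")
  )
  if (variant == "fixed_course") {
    if (is.null(log$scans)) {
      stop("fixed_course variant requires proximity scans on the log")
    }
    damped <- damp_log(log, dlaff_cfg)
    obst <- proximity_bias_feature(s[c("t", "speed", "turn")],
                                   damped$corrected,
                                   sample_rate_hz = rate, deadband = deadband)
    out <- c(out,
             obst_fl = unname(obst["forward_left"]),
             obst_fr = unname(obst["forward_right"]),
             obst_rl = unname(obst["rear_left"]),
             obst_rr = unname(obst["rear_right"]),
             drive_ratio = tm$ratio,
             total_time_s = tm$total_s)
    out <- out[fixed_course_fields]
  } else {
    out <- c(out, drive_ratio = tm$ratio)
    out <- out[long_term_fields]
  }
  structure(out, variant = variant, class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s variant, %d features\n",
              attr(x, "variant"), length(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Fixed-course feature table for the 14 course participants
#'
#' The published feature table of the confined-space driving course: 14
#' participants (12 wheelchair users plus 2 novice controls), 4 timed runs
#' each, 20 features per run (median values). Column names follow the
#' quadrant abbreviation scheme (`fra` = forward-right ellipse `a`, etc.);
#' `smoothness` is the score x 100, `drive_pct` the percentage of the run
#' spent in motion and `total_s` the course time in seconds.
#'
#' @return A 56-row data.frame with `id`, `run` and the 20 feature columns.
#' @export
fixed_course_features <- function() {
  path <- system.file("extdata", "fixed_course_features.csv",
                      package = "wheelfeat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Self-reported collision diaries (good day / bad day)
#'
#' Per-obstacle, per-class collision counts self-reported by the 11
#' questionnaire participants for one self-defined good day and one bad day.
#' Classes: `A` accidental, `D` deliberate (e.g. pushing doors open),
#' `C` misalignment (reverse-and-reapproach). `NA` marks participants unable
#' to drive or questions not answered.
#'
#' @param day `"good"` or `"bad"`.
#' @return List with `counts` (data.frame `obstacle`, `class`, one column per
#'   participant) and `hours_in_pwc` (named numeric, hours).
#' @export
collision_diary <- function(day = c("good", "bad")) {
  day <- match.arg(day)
  path <- system.file("extdata", paste0("collisions_", day, "_day.csv"),
                      package = "wheelfeat", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  hours_row <- d$class == "H"
  counts <- d[!hours_row, ]
  hours <- as.numeric(d[hours_row, -(1:2)])
  names(hours) <- names(d)[-(1:2)]
  list(counts = counts, hours_in_pwc = hours)
}

#' Long-term collision monitoring data
#'
#' Button-press collision counts and exposure hours for the two participants
#' monitored over three days of ordinary home use.
#'
#' @return A data.frame with `id`, `day`, `deliberate`, `accidental`,
#'   `hours_in_pwc`, `hours_driving`.
#' @export
longterm_collisions <- function() {
  path <- system.file("extdata", "longterm_collisions.csv",
                      package = "wheelfeat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
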