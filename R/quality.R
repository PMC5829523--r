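#' Spectrum analysis configuration
#'
#' Settings for the tremor FFT: taper, analysis band and detrending. The
#' default band of 0.5-15 Hz covers the physiological hand-tremor range
#' (typically 4-11 Hz) with margin on both sides while excluding DC and the
#' slow voluntary-steering component.
#'
#' @param window taper name; `"hann"` or `"rect"`.
#' @param min_freq_hz,max_freq_hz analysis band bounds, Hz;
#'   `0 < min < max <= Nyquist` is enforced at analysis time.
#' @param detrend remove the signal mean before transforming?
#' @return A list of class `spectrum_config`.
#' @export
spectrum_config <- function(window = "hann", min_freq_hz = 0.5,
                            max_freq_hz = 15, detrend = TRUE) {
  stopifnot(min_freq_hz > 0, max_freq_hz > min_freq_hz)
  window <- match.arg(window, c("hann", "rect"))
  structure(list(window = window, min_freq_hz = min_freq_hz,
                 max_freq_hz = max_freq_hz, detrend = detrend),
            class = "spectrum_config")
}

#' Dominant tremor frequency by FFT
#'
#' Discrete Fourier transform of one joystick axis; the dominant in-band bin
#' gives the tremor frequency estimate and its amplitude. The signal is
#' mean-removed (when `cfg$detrend`), Hann-tapered and zero-padded to the next
#' power of two; DC is always excluded. A signal with no in-band energy
#' (e.g. a constant stick position) is flagged as no tremor and reported as
#' frequency 0.
#'
#' @param signal numeric axis samples (counts).
#' @param sample_rate_hz sampling rate, Hz.
#' @param cfg a [spectrum_config].
#' @param axis label recorded in the result (`"speed"` is the y axis of the
#'   stick and the default tremor axis).
#' @return A list of class `tremor_result`: `f_fft_hz`, `magnitude`,
#'   `no_tremor` flag, `bin_width_hz`, `axis`.
#' @examples
#' t <- seq(0, 10, by = 1 / 50)
#' res <- fft_dominant_frequency(20 * sin(2 * pi * 6 * t), 50)
#' res$f_fft_hz
#' @export
fft_dominant_frequency <- function(signal, sample_rate_hz,
                                   cfg = spectrum_config(), axis = "speed") {
  n <- length(signal)
  if (n < 2 * sample_rate_hz) {
    stop("insufficient data: need at least 2 s of samples for 0.5 Hz resolution")
  }
  x <- as.numeric(signal)
  if (isTRUE(cfg$detrend)) x <- x - mean(x)
  if (cfg$window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * w
  }
  nfft <- 2^ceiling(log2(n))
  spec <- abs(stats::fft(c(x, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * sample_rate_hz / nfft
  band <- which(freq >= cfg$min_freq_hz &
                  freq <= min(cfg$max_freq_hz, sample_rate_hz / 2) & freq > 0)
  bin_width <- sample_rate_hz / nfft
  if (length(band) == 0L || max(spec[band]) <= .Machine$double.eps * n) {
    return(structure(list(f_fft_hz = 0, magnitude = 0, no_tremor = TRUE,
                          bin_width_hz = bin_width, axis = axis),
                     class = "tremor_result"))
  }
  k <- band[which.max(spec[band])]
  structure(list(f_fft_hz = freq[k], magnitude = spec[k] / n,
                 no_tremor = FALSE, bin_width_hz = bin_width, axis = axis),
            class = "tremor_result")
}

#' @export
print.tremor_result <- function(x, ...) {
  if (x$no_tremor) {
    cat("<tremor_result> no in-band tremor (axis ", x$axis, ")\n", sep = "")
  } else {
    cat(sprintf("<tremor_result> %.3f Hz (magnitude %.3g, bin %.3g Hz, axis %s)\n",
                x$f_fft_hz, x$magnitude, x$bin_width_hz, x$axis))
  }
  invisible(x)
}

#' Tremor frequency by peak counting
#'
#' Real-time-capable alternative to the FFT: remove the mean, then count
#' local extrema between successive zero crossings. A sinusoid contributes
#' two extrema per cycle, so frequency = extrema / (2 x duration). Sudden
#' direction changes (spasms, panic corrections) also register as extrema,
#' which is what makes this estimator useful for jerk-like events.
#'
#' @param signal numeric axis samples (counts).
#' @param sample_rate_hz sampling rate, Hz.
#' @return Estimated frequency, Hz (0 for a constant signal).
#' @export
peak_count_frequency <- function(signal, sample_rate_hz) {
  n <- length(signal)
  if (n < 2 * sample_rate_hz) {
    stop("insufficient data: need at least 2 s of samples")
  }
  x <- as.numeric(signal) - mean(signal)
  duration_s <- n / sample_rate_hz
  sgn <- sign(x)
  sgn[sgn == 0] <- 1L
  crossings <- which(diff(sgn) != 0)
  if (length(crossings) == 0L) return(0)
  # local extrema: sign changes of the first difference, counted only inside
  # the zero-crossing spans (tails before the first / after the last crossing
  # are open half-cycles)
  dx <- diff(x)
  dsgn <- sign(dx)
  dsgn[dsgn == 0] <- 1L
  ext <- which(diff(dsgn) != 0) + 1L
  span <- range(crossings)
  n_ext <- sum(ext >= span[1] & ext <= span[2] + 1L)
  n_ext <- max(n_ext, length(crossings) - 1L)  # >= one extremum per half-cycle
  n_ext / (2 * duration_s)
}

#' Per-step joystick velocity-vector magnitude
#'
#' The distance the joystick tip moved in the (turn, speed) plane between two
#' samples, per unit time: `sqrt((v2-v1)^2 + (w2-w1)^2) / (t2-t1)`, in
#' counts per second. This is the per-step quantity the smoothness score
#' averages.
#'
#' @param p1,p2 length-2 numeric vectors `c(speed, turn)` at times `t1 < t2`.
#' @param t1,t2 sample times, seconds.
#' @return Non-negative rate, counts/s.
#' @export
smoothness_lambda <- function(p1, p2, t1, t2) {
  if (t2 <= t1) stop("t2 must be greater than t1")
  sqrt((p2[1] - p1[1])^2 + (p2[2] - p1[2])^2) / (t2 - t1)
}

#' Joystick velocity-vector smoothness score
#'
#' The score is a weighted average of the per-step velocity-vector magnitudes,
#' `Lambda = sum(w_i * lambda_i) / sum(w_i)` with `w_i` the running median of
#' `lambda_1..lambda_i`. The running-median weight de-emphasises the first,
#' unsettled steps of a movement and tracks the typical step size, so isolated
#' large excursions raise the score without dominating it. Higher values mean
#' jerkier input; published summaries print `Lambda x 100`.
#'
#' When the joystick bus data (50 Hz) is compared against a direct high-rate
#' analogue measurement, a calibration factor of 2 aligns the two scales;
#' this is applied only through the explicit `scale_factor` argument, never
#' silently.
#'
#' @param samples data.frame with columns `t` (ms), `speed`, `turn` (counts),
#'   e.g. `log$samples` or a segment slice.
#' @param scale_factor calibration multiplier applied to the final score.
#' @return A list of class `smoothness_result`: `lambda_series` (counts/s, one
#'   per step), `score` (Lambda, after scaling), `scale_factor`.
#' @examples
#' s <- data.frame(t = seq(0, 980, by = 20), speed = seq(0, 98, by = 2), turn = 0)
#' smoothness_score(s)$score  # constant-rate sweep: Lambda equals the rate
#' @export
smoothness_score <- function(samples, scale_factor = 1) {
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  dt <- diff(samples$t) / 1000
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  lam <- sqrt(diff(samples$speed)^2 + diff(samples$turn)^2) / dt
  w <- running_median(lam)
  score <- if (sum(w) == 0) 0 else sum(w * lam) / sum(w)
  structure(list(lambda_series = lam, score = score * scale_factor,
                 scale_factor = scale_factor),
            class = "smoothness_result")
}

#' @export
print.smoothness_result <- function(x, ...) {
  cat(sprintf("<smoothness_result> Lambda = %.4g (x100 = %.3g) over %d steps%s\n",
              x$score, 100 * x$score, length(x$lambda_series),
              if (x$scale_factor != 1) sprintf(", scale %g", x$scale_factor) else ""))
  invisible(x)
}

# running median of x[1..i] for each i
running_median <- function(x) {
  vapply(seq_along(x), function(i) stats::median(x[seq_len(i)]), numeric(1))
}
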