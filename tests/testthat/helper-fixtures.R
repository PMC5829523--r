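# shared fixture builders; everything is generated in code

# uniform 50 Hz log from explicit axis vectors
make_log <- function(speed, turn = rep(0, length(speed)), rate = 50, ...) {
  joystick_log(t = (seq_along(speed) - 1L) * (1000 / rate),
               speed = speed, turn = turn, sample_rate_hz = rate, ...)
}

# pure sinusoid sampled at `rate` for `dur` seconds
sine_signal <- function(freq_hz, dur_s = 10, rate = 50, amp = 20, phase = 0) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  amp * sin(2 * pi * freq_hz * t + phase)
}

# log whose motion mask equals `mask` (moving samples get speed 50)
mask_log <- function(mask, rate = 50) {
  make_log(ifelse(mask, 50, 0), rate = rate)
}

# independent run-length oracle for segment extraction: bridge short gaps,
# then keep long runs -- written directly from the definition
oracle_segments <- function(mask, rate, min_s, merge_s) {
  n <- length(mask)
  bridged <- mask
  i <- 1L
  while (i <= n) {
    if (!bridged[i]) {
      j <- i
      while (j <= n && !bridged[j]) j <- j + 1L
      gap_len <- j - i
      interior <- i > 1L && j <= n
      if (interior && gap_len / rate < merge_s) bridged[i:(j - 1L)] <- TRUE
      i <- j
    } else i <- i + 1L
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (bridged[i]) {
      j <- i
      while (j <= n && bridged[j]) j <- j + 1L
      if ((j - i) / rate >= min_s) segs[[length(segs) + 1L]] <- c(i, j - 1L)
      i <- j
    } else i <- i + 1L
  }
  segs
}
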