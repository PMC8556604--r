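# Windowed-sinc FIR filtering and line-noise removal.

#' Design a Hamming-window FIR filter
#'
#' Linear-phase windowed-sinc design. The number of taps follows the
#' heuristic `taps = ceil_to_even(3.3 / (tb / srate)) + 1` with transition
#' bandwidth `tb = 2 * |passband_edge - cutoff_minus6db|`; the realised
#' -6 dB point of a Hamming windowed-sinc filter falls at the requested
#' cutoff. The high-pass variant (1 Hz passband edge, 0.75 Hz -6 dB cutoff
#' at 512 Hz) yields 3381 taps.
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param passband_edge_hz edge of the passband, Hz.
#' @param cutoff_minus6db_hz frequency of the -6 dB point, Hz.
#' @param srate sampling rate, Hz.
#' @return a list of class `fir_spec` with the design fields and the
#'   coefficient vector `h`.
#' @export
design_fir <- function(kind = c("highpass", "lowpass"),
                       passband_edge_hz, cutoff_minus6db_hz, srate) {
  kind <- match.arg(kind)
  tb <- 2 * abs(passband_edge_hz - cutoff_minus6db_hz)
  if (tb <= 0)
    abort("transition band must be positive", "icaclean_parameter_error")
  if (cutoff_minus6db_hz <= 0 || cutoff_minus6db_hz >= srate / 2)
    abort("cutoff must lie in (0, Nyquist)", "icaclean_parameter_error")
  order <- 3.3 / (tb / srate)
  order <- 2 * ceiling(order / 2)               # round up to even order
  taps <- as.integer(order + 1)
  # windowed sinc low-pass at the -6 dB cutoff, unit DC gain
  mid <- (taps - 1) / 2
  k <- seq(0, taps - 1) - mid
  fc <- cutoff_minus6db_hz / srate
  sinc <- ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, taps - 1) / (taps - 1))
  h <- 2 * fc * sinc * w
  h <- h / sum(h)
  if (kind == "highpass") {                     # spectral inversion
    h <- -h
    h[mid + 1] <- h[mid + 1] + 1
  }
  structure(list(kind = kind, passband_edge_hz = passband_edge_hz,
                 cutoff_minus6db_hz = cutoff_minus6db_hz,
                 transition_bw_hz = tb, taps = taps, window = "hamming",
                 srate = srate, h = h),
            class = "fir_spec")
}

# Realised amplitude response of a linear-phase FIR at given frequencies.
fir_response <- function(filt, freqs_hz) {
  h <- filt$h
  n <- seq_along(h) - (length(h) + 1) / 2       # centred taps
  vapply(freqs_hz, function(f) {
    abs(sum(h * cos(2 * pi * f / filt$srate * n)))
  }, numeric(1))
}

# Zero-phase single pass: FFT convolution with reflection padding and
# group-delay compensation (h is symmetric, so one aligned pass is
# phase-free; two passes give the forward-backward magnitude response).
fir_pass <- function(x, h) {
  nh <- length(h)
  half <- (nh - 1) / 2
  np <- min(length(x) - 1, nh)
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]),        # reflected edges
          x,
          2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1)]))
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(np + half + 1):(np + half + length(x))]
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application (the filter is run twice, so the amplitude
#' response is squared and the phase is identically zero). Output length
#' equals input length.
#'
#' @param eeg an [continuous_eeg()] object.
#' @param filt a `fir_spec` from [design_fir()].
#' @return the filtered `eeg_continuous`.
#' @export
apply_fir_zero_phase <- function(eeg, filt) {
  if (n_samples(eeg) <= 3 * filt$taps)
    abort("signal too short for this filter (need > 3 x taps samples)",
          "icaclean_length_error")
  out <- eeg
  for (i in seq_len(n_channels(eeg))) {
    y <- fir_pass(eeg$data[i, ], filt$h)
    out$data[i, ] <- fir_pass(y, filt$h)
  }
  out
}

#' Remove power-line noise
#'
#' Fits and subtracts sine/cosine terms at the line frequency and its first
#' harmonic in consecutive 4-s chunks, which tracks slow amplitude and phase
#' drift of the interference while leaving broadband activity untouched.
#'
#' @param eeg an [continuous_eeg()] object.
#' @param line_freq_hz line frequency, Hz (default 50).
#' @param chunk_s regression chunk length in seconds (default 4).
#' @return the cleaned `eeg_continuous`.
#' @export
remove_line_noise <- function(eeg, line_freq_hz = 50, chunk_s = 4) {
  if (line_freq_hz >= eeg$srate / 2)
    abort("line frequency must be below Nyquist",
          "icaclean_parameter_error")
  n <- n_samples(eeg)
  clen <- max(2L, as.integer(round(chunk_s * eeg$srate)))
  starts <- seq(1L, n, by = clen)
  t <- seq_len(n) / eeg$srate
  freqs <- c(line_freq_hz, 2 * line_freq_hz)
  freqs <- freqs[freqs < eeg$srate / 2]
  out <- eeg
  for (s in starts) {
    idx <- s:min(s + clen - 1L, n)
    if (length(idx) < 8L) next
    X <- do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))))
    # one least-squares solve for all channels at once
    coefs <- qr.solve(X, t(eeg$data[, idx, drop = FALSE]))
    out$data[, idx] <- eeg$data[, idx, drop = FALSE] - t(X %*% coefs)
  }
  out
}
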