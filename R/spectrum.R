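# Welch spectral estimation for component sources.

#' Estimate a component's log power spectrum
#'
#' Welch estimate with 1-s Hamming windows, 50 % overlap, and 2x zero
#' padding (grid spacing 0.5 Hz at integer sampling rates). `log_power` is
#' the natural log of the averaged periodogram.
#'
#' @param source numeric vector, a component time course.
#' @param srate sampling rate, Hz.
#' @param fit_band_hz numeric length-2, the band later used for the 1/f fit
#'   (default `c(2, 20)`, the infant-mode setting; stored on the object).
#' @return a list of class `spectral_estimate` with `freqs_hz`, `log_power`
#'   and `fit_band_hz`.
#' @export
estimate_spectrum <- function(source, srate, fit_band_hz = c(2, 20)) {
  if (length(source) < 10 * srate)
    abort("need at least 10 s of signal", "icaclean_length_error")
  if (fit_band_hz[2] >= srate / 2 || fit_band_hz[1] <= 0)
    abort("fit band must lie inside (0, Nyquist)",
          "icaclean_parameter_error")
  win <- as.integer(round(srate))
  hop <- win %/% 2L
  nfft <- 2L * win
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  starts <- seq(1L, length(source) - win + 1L, by = hop)
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- source[s:(s + win - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(c(seg, numeric(nfft - win))))^2
    acc <- acc + sp[seq_len(nfft %/% 2L + 1L)]
  }
  psd <- acc / (length(starts) * u * srate)
  freqs <- seq(0, nfft %/% 2L) * srate / nfft
  structure(list(freqs_hz = freqs,
                 log_power = log(psd + .Machine$double.xmin),
                 fit_band_hz = fit_band_hz),
            class = "spectral_estimate")
}
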