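# The six component features used for classification.
#
# Each feature is invariant to joint positive rescaling of a component's
# (pattern, source) pair and to sign flips, because patterns are normalised
# before feature extraction and the time-course features use absolute or
# log-spectral statistics.

#' Current density norm of a scalp pattern
#'
#' Log Euclidean norm of the depth-weighted minimum-norm current-density
#' estimate of the pattern on a fixed 642-dipole spherical grid under a
#' three-shell spherical head model. Focal, physiologically implausible
#' patterns require large source currents, so larger values indicate
#' artifact.
#'
#' @param pattern numeric scalp map (one mixing-matrix column); normalised
#'   internally.
#' @param montage electrode montage matching the pattern.
#' @return scalar feature value.
#' @export
feat_current_density_norm <- function(pattern, montage = standard_montage_32()) {
  nrm <- sqrt(sum(pattern^2))
  if (nrm == 0)
    abort("pattern must be non-zero", "icaclean_degenerate_pattern_error")
  j <- current_density_estimate(pattern / nrm, montage)
  log(sqrt(sum(j^2)))
}

#' Log range of a normalised scalp pattern
#'
#' `log(max(pattern) - min(pattern))`. The pattern is expected to be a
#' normalised mixing-matrix column; single-electrode patterns then have a
#' large range relative to smooth dipolar maps.
#'
#' @param pattern numeric scalp map (unit norm by convention).
#' @return scalar feature value.
#' @export
feat_range_within_pattern <- function(pattern) {
  rng <- range(pattern)
  if (diff(rng) == 0)
    abort("constant pattern has no range",
          "icaclean_degenerate_pattern_error")
  log(diff(rng))
}

#' Mean local absolute skewness of a source time course
#'
#' The source is cut into consecutive non-overlapping windows (default
#' 15 s) and the mean of the absolute sample skewness over windows is
#' returned. Blink-like sources with sparse unidirectional pulses score
#' high.
#'
#' @param source numeric component time course.
#' @param srate sampling rate, Hz.
#' @param window_s window length in seconds.
#' @return scalar feature value.
#' @export
feat_mean_local_skewness <- function(source, srate, window_s = 15) {
  win <- as.integer(round(window_s * srate))
  if (length(source) < win)
    abort("source shorter than one skewness window",
          "icaclean_length_error")
  nwin <- floor(length(source) / win)
  sk <- vapply(seq_len(nwin), function(k) {
    seg <- source[((k - 1L) * win + 1L):(k * win)]
    abs(e1071::skewness(seg, type = 1))
  }, numeric(1))
  mean(sk)
}

#' 1/f^lambda spectral fit
#'
#' Least-squares fit of `log_power ~ a - lambda * log(f)` over the
#' spectrum's fit band. Returns the exponent and the mean squared residual.
#'
#' @param spec a `spectral_estimate` from [estimate_spectrum()].
#' @return named numeric vector with elements `lambda` and `fit_error`.
#' @export
feat_spectral_fit <- function(spec) {
  sel <- spec$freqs_hz >= spec$fit_band_hz[1] &
    spec$freqs_hz <= spec$fit_band_hz[2]
  if (sum(sel) < 8)
    abort("fit band covers fewer than 8 grid points",
          "icaclean_parameter_error")
  lf <- log(spec$freqs_hz[sel])
  lp <- spec$log_power[sel]
  fit <- stats::lm.fit(cbind(1, -lf), lp)
  c(lambda = unname(fit$coefficients[2]),
    fit_error = mean(fit$residuals^2))
}

#' Mean log power in the alpha band
#'
#' Mean of `log_power` over grid frequencies inside `alpha_band`
#' (inclusive). Infant mode uses 6-9 Hz, adult mode 8-13 Hz.
#'
#' @param spec a `spectral_estimate`.
#' @param alpha_band numeric length-2 band in Hz.
#' @return scalar feature value.
#' @export
feat_alpha_power <- function(spec, alpha_band = c(6, 9)) {
  sel <- spec$freqs_hz >= alpha_band[1] & spec$freqs_hz <= alpha_band[2]
  if (!any(sel))
    abort("alpha band contains no grid frequencies",
          "icaclean_parameter_error")
  mean(spec$log_power[sel])
}

mode_bands <- function(mode = c("infant", "adult")) {
  mode <- match.arg(mode)
  if (mode == "infant") list(alpha = c(6, 9), fit = c(2, 20))
  else list(alpha = c(8, 13), fit = c(2, 40))
}

#' Extract the six classification features for every component
#'
#' @param ica an [ica_decomposition()] (normalised on construction).
#' @param montage electrode montage for the scalp patterns.
#' @param mode `"infant"` (alpha 6-9 Hz, fit band 2-20 Hz) or `"adult"`
#'   (alpha 8-13 Hz, fit band 2-40 Hz).
#' @param skew_window_s local-skewness window, seconds.
#' @return data.frame with `component_id`, the six feature columns, and a
#'   logical `flagged` column marking components whose features could not
#'   be computed (their feature values are NA).
#' @export
extract_features <- function(ica, montage = standard_montage_32(),
                             mode = c("infant", "adult"),
                             skew_window_s = 15) {
  mode <- match.arg(mode)
  bands <- mode_bands(mode)
  ncomp <- ncol(ica$mixing)
  rows <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    rows[[k]] <- tryCatch({
      pattern <- ica$mixing[, k]
      source <- ica$sources[k, ]
      # unit-variance source: all spectral features describe the *shape*
      # of the spectrum, not the component's scale, so features agree
      # between isolated training components and ICA-estimated ones
      ssd <- stats::sd(source)
      if (ssd > 0) source <- source / ssd
      spec <- estimate_spectrum(source, ica$srate, bands$fit)
      fit <- feat_spectral_fit(spec)
      data.frame(
        component_id = k,
        current_density_norm = feat_current_density_norm(pattern, montage),
        range_within_pattern = feat_range_within_pattern(pattern),
        mean_local_skewness = feat_mean_local_skewness(source, ica$srate,
                                                       skew_window_s),
        lambda = fit[["lambda"]],
        fit_error = fit[["fit_error"]],
        alpha_band_power = feat_alpha_power(spec, bands$alpha),
        flagged = FALSE
      )
    }, icaclean_error = function(e) {
      data.frame(component_id = k, current_density_norm = NA_real_,
                 range_within_pattern = NA_real_,
                 mean_local_skewness = NA_real_, lambda = NA_real_,
                 fit_error = NA_real_, alpha_band_power = NA_real_,
                 flagged = TRUE)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "alpha_band") <- bands$alpha
  out
}
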