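# Event-locked ERP analysis: epoching, baseline correction, ROI averaging
# and adaptive-mean peak amplitudes.

#' ERP analysis configuration
#'
#' Defaults: epochs from -1.0 to +0.8 s around the event, baseline window
#' -1.0 to -0.7 s, ROI clusters over the frontal pole / central / occipital
#' electrodes, measure windows -0.1..0.1 s (frontal pole, saccade artifact)
#' and 0.2..0.3 s (central and occipital, visual response), adaptive search
#' half-width 50 ms and averaging half-width 10 ms.
#'
#' @param epoch_window_s numeric length-2, epoch bounds in seconds.
#' @param baseline_window_s numeric length-2, baseline bounds in seconds.
#' @param rois named list of electrode-name vectors.
#' @param measure_windows_s named list of numeric length-2 measure windows,
#'   same names as `rois`.
#' @param adaptive_search_halfwidth_s peak-search half-width, s.
#' @param adaptive_mean_halfwidth_s averaging half-width around the peak, s.
#' @return a list of class `erp_config`.
#' @export
erp_config <- function(epoch_window_s = c(-1.0, 0.8),
                       baseline_window_s = c(-1.0, -0.7),
                       rois = list(frontal_pole = c("Fp1", "Fp2", "AF3", "AF4"),
                                   central = c("C3", "Cz", "C4"),
                                   occipital = c("O1", "Oz", "O2")),
                       measure_windows_s = list(frontal_pole = c(-0.1, 0.1),
                                                central = c(0.2, 0.3),
                                                occipital = c(0.2, 0.3)),
                       adaptive_search_halfwidth_s = 0.05,
                       adaptive_mean_halfwidth_s = 0.01) {
  if (adaptive_search_halfwidth_s <= 0 || adaptive_mean_halfwidth_s <= 0)
    abort("adaptive half-widths must be positive",
          "icaclean_parameter_error")
  if (baseline_window_s[1] < epoch_window_s[1] ||
      baseline_window_s[2] > epoch_window_s[2])
    abort("baseline window must lie inside the epoch window",
          "icaclean_parameter_error")
  structure(list(epoch_window_s = epoch_window_s,
                 baseline_window_s = baseline_window_s,
                 rois = rois, measure_windows_s = measure_windows_s,
                 adaptive_search_halfwidth_s = adaptive_search_halfwidth_s,
                 adaptive_mean_halfwidth_s = adaptive_mean_halfwidth_s),
            class = "erp_config")
}

#' Extract event-locked epochs
#'
#' Events whose epoch window leaves the recording or overlaps rejected
#' samples are dropped and reported in the `dropped_events` attribute.
#'
#' @param eeg an [continuous_eeg()] object.
#' @param event_latencies_s numeric vector of event times in seconds.
#' @param config an [erp_config()].
#' @return a 3-D array (events x channels x time) with the time axis (s,
#'   relative to the event) in attribute `time_s` and channel names in
#'   `dimnames`.
#' @export
epoch_eeg <- function(eeg, event_latencies_s, config = erp_config()) {
  srate <- eeg$srate
  rel <- seq(round(config$epoch_window_s[1] * srate),
             round(config$epoch_window_s[2] * srate))
  time_s <- rel / srate
  n <- n_samples(eeg)
  keep <- logical(length(event_latencies_s))
  idx_list <- vector("list", length(event_latencies_s))
  for (k in seq_along(event_latencies_s)) {
    ctr <- round(event_latencies_s[k] * srate) + 1L
    idx <- ctr + rel
    ok <- idx[1] >= 1L && idx[length(idx)] <= n &&
      !any(eeg$rejected_mask[idx])
    keep[k] <- ok
    if (ok) idx_list[[k]] <- idx
  }
  if (!any(keep))
    abort("no events survive epoching", "icaclean_empty_epochs_error")
  ep <- array(0, dim = c(sum(keep), n_channels(eeg), length(rel)),
              dimnames = list(NULL, eeg$channel_names, NULL))
  i <- 0L
  for (k in which(keep)) {
    i <- i + 1L
    ep[i, , ] <- eeg$data[, idx_list[[k]]]
  }
  attr(ep, "time_s") <- time_s
  attr(ep, "dropped_events") <- which(!keep)
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window.
#'
#' @param epochs array from [epoch_eeg()].
#' @param config an [erp_config()].
#' @return the corrected epochs array.
#' @export
baseline_correct <- function(epochs, config = erp_config()) {
  time_s <- attr(epochs, "time_s")
  sel <- time_s >= config$baseline_window_s[1] &
    time_s <= config$baseline_window_s[2]
  if (!any(sel))
    abort("baseline window outside the epoch", "icaclean_parameter_error")
  base <- apply(epochs[, , sel, drop = FALSE], c(1, 2), mean)
  out <- sweep(epochs, c(1, 2), base)
  attributes(out) <- attributes(epochs)
  out
}

#' Average epochs over an ROI
#'
#' Mean over epochs, then over the ROI channels (the order does not matter
#' by linearity).
#'
#' @param epochs array from [epoch_eeg()].
#' @param roi character vector of electrode names.
#' @return numeric waveform with attribute `time_s`.
#' @export
roi_average <- function(epochs, roi) {
  chans <- dimnames(epochs)[[2]]
  m <- match(roi, chans)
  if (anyNA(m))
    abort(paste("unknown ROI electrode(s):",
                paste(roi[is.na(m)], collapse = ", ")),
          "icaclean_roi_error")
  avg <- apply(epochs[, m, , drop = FALSE], 3, mean)
  attr(avg, "time_s") <- attr(epochs, "time_s")
  avg
}

#' Adaptive-mean peak amplitude
#'
#' Finds the sample of maximum absolute amplitude within
#' `center +/- adaptive_search_halfwidth_s` (earliest sample on ties) and
#' returns the mean amplitude in a window of
#' `+/- adaptive_mean_halfwidth_s` around that peak.
#'
#' @param waveform numeric vector with attribute `time_s` (e.g. from
#'   [roi_average()]).
#' @param window_center_s centre of the search window, seconds.
#' @param config an [erp_config()].
#' @return named numeric vector `c(peak_latency_s, amplitude_uV)`.
#' @export
adaptive_mean_amplitude <- function(waveform, window_center_s,
                                    config = erp_config()) {
  time_s <- attr(waveform, "time_s")
  if (is.null(time_s))
    abort("waveform needs a time_s attribute", "icaclean_parameter_error")
  hw <- config$adaptive_search_halfwidth_s
  eps <- 1e-9
  sel <- which(time_s >= window_center_s - hw - eps &
               time_s <= window_center_s + hw + eps)
  if (length(sel) == 0)
    abort("search window outside the waveform support",
          "icaclean_parameter_error")
  peak_i <- sel[which.max(abs(waveform[sel]))]
  mw <- config$adaptive_mean_halfwidth_s
  msel <- which(time_s >= time_s[peak_i] - mw - eps &
                time_s <= time_s[peak_i] + mw + eps)
  c(peak_latency_s = time_s[peak_i],
    amplitude_uV = mean(waveform[msel]))
}
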