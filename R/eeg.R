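# Continuous multichannel EEG container.

#' Construct a continuous EEG object
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per row of `data`.
#' @param montage_ref optional identifier of the montage the channels refer to
#'   (default `"std32"`).
#' @param rejected_mask logical vector, one element per sample; `TRUE` marks
#'   samples removed by gross-epoch rejection. Defaults to all-`FALSE`.
#' @return an object of class `eeg_continuous`.
#' @export
continuous_eeg <- function(data, srate, channel_names,
                           montage_ref = "std32", rejected_mask = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names))
    abort("nrow(data) must equal length(channel_names)",
          "icaclean_eeg_error")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    abort("srate must be a positive scalar", "icaclean_eeg_error")
  if (is.null(rejected_mask)) rejected_mask <- rep(FALSE, ncol(data))
  if (length(rejected_mask) != ncol(data))
    abort("rejected_mask length must equal the number of samples",
          "icaclean_eeg_error")
  rownames(data) <- as.character(channel_names)
  structure(list(data = data, srate = srate,
                 channel_names = as.character(channel_names),
                 montage_ref = montage_ref,
                 rejected_mask = as.logical(rejected_mask)),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (%.1f s), %d samples rejected\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, sum(x$rejected_mask)))
  invisible(x)
}

n_samples <- function(eeg) ncol(eeg$data)
n_channels <- function(eeg) nrow(eeg$data)

# Data with rejected samples dropped.
retained_data <- function(eeg) eeg$data[, !eeg$rejected_mask, drop = FALSE]
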