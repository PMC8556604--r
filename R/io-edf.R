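# EDF (16-bit) and BDF (24-bit) readers and an EDF writer.
#
# Both formats share the same ASCII header layout: a 256-byte fixed header
# followed by 256 bytes of per-signal fields, then fixed-duration data
# records with little-endian integer samples (2 bytes for EDF, 3 for BDF).
# Physical values are recovered by the standard linear gain/offset mapping.

.trigger_labels <- c("status", "trigger", "trig", "edf annotations",
                     "bdf annotations", "marker")

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  trimws(rawToChar(raw))
}

#' Read a continuous EEG recording from a BDF or EDF file
#'
#' Channel names are matched case-insensitively against the standard
#' 32-channel 10-20 montage; unmatched channels are kept in the data but
#' listed in the `unmatched_channels` attribute. Trigger/annotation channels
#' (e.g. "Status") are excluded from the data and reported in the
#' `excluded_channels` attribute. Samples are returned in microvolts.
#'
#' @param path path to the file.
#' @param format `"bdf"`, `"edf"`, or `"auto"` (default: decide from the
#'   header magic byte).
#' @return an [continuous_eeg()] object.
#' @export
read_continuous_eeg <- function(path, format = c("auto", "bdf", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "icaclean_format_error")
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", n = 8)
  if (format == "auto")
    format <- if (magic[1] == as.raw(0xff)) "bdf" else "edf"
  bytes_per_sample <- if (format == "bdf") 3L else 2L

  read_ascii_skip <- function(n) read_ascii(con, n)
  read_ascii_skip(80); read_ascii_skip(80)   # patient, recording id
  read_ascii_skip(8); read_ascii_skip(8)     # start date, time
  header_bytes <- as.integer(read_ascii_skip(8))
  read_ascii_skip(44)                        # reserved
  n_records <- as.integer(read_ascii_skip(8))
  record_dur <- as.numeric(read_ascii_skip(8))
  ns <- as.integer(read_ascii_skip(4))
  if (is.na(ns) || ns < 1 || is.na(n_records))
    abort("unreadable EDF/BDF header", "icaclean_format_error")

  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- fld(16)
  fld(80)                                    # transducer
  fld(8)                                     # physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                                    # prefilter
  spr <- as.integer(fld(8))                  # samples per record
  fld(32)                                    # reserved
  seek(con, header_bytes)

  if (anyNA(pmin) || anyNA(pmax) || anyNA(spr))
    abort("unreadable EDF/BDF signal headers", "icaclean_format_error")
  if (length(unique(spr)) != 1L)
    abort("mixed sampling rates per record are not supported",
          "icaclean_format_error")
  srate <- spr[1] / record_dur

  total <- sum(spr) * n_records
  if (format == "bdf") {
    raw <- readBin(con, "raw", n = total * 3L)
    m <- matrix(as.integer(raw), nrow = 3L)
    vals <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    vals <- ifelse(vals >= 8388608, vals - 16777216, vals)
  } else {
    vals <- readBin(con, integer(), n = total, size = 2L, signed = TRUE,
                    endian = "little")
  }
  # records are blocks of [sig1 spr samples, sig2 spr samples, ...]
  arr <- array(vals, dim = c(spr[1], ns, n_records))
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_records)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns))
    data[i, ] <- as.numeric(arr[, i, ]) * gain[i] +
      (pmin[i] - dmin[i] * gain[i])

  is_trig <- tolower(labels) %in% .trigger_labels
  excluded <- labels[is_trig]
  data <- data[!is_trig, , drop = FALSE]
  labels <- labels[!is_trig]
  if (nrow(data) < 2)
    abort("fewer than 2 data channels", "icaclean_format_error")

  std <- standard_montage_32()
  m <- match(tolower(labels), tolower(std$names))
  labels[!is.na(m)] <- std$names[m[!is.na(m)]]
  if (all(is.na(m)))
    abort("no channel labels match the 10-20 montage",
          "icaclean_montage_error")

  eeg <- continuous_eeg(data, srate, labels)
  attr(eeg, "excluded_channels") <- excluded
  attr(eeg, "unmatched_channels") <- labels[is.na(m)]
  eeg
}

fmt_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

fmt_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = -1)
  fmt_field(s, width)
}

#' Write a continuous EEG recording to an EDF file
#'
#' Signals are stored as 16-bit integers with a symmetric physical range per
#' channel, so the round-trip error is bounded by one quantisation step. The
#' record duration is 1 s; a trailing partial second is zero-padded.
#'
#' @param eeg an [continuous_eeg()] object (microvolts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_continuous_eeg <- function(eeg, path) {
  data <- eeg$data
  srate <- eeg$srate
  if (abs(srate - round(srate)) > 1e-9)
    abort("EDF writer requires an integer sampling rate",
          "icaclean_format_error")
  srate <- as.integer(round(srate))
  nch <- nrow(data)
  n_records <- as.integer(ceiling(ncol(data) / srate))
  pad <- n_records * srate - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, nch, pad))

  pmax <- apply(abs(data), 1, max)
  pmax[pmax == 0] <- 1
  pmax <- signif(pmax * 1.0001, 6)           # text-exact symmetric range
  scale <- pmax / 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(fmt_field(s, w)), con)
  wr("0", 8)
  wr("icaclean export", 80)
  wr("icaclean", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256L + 256L * nch), 8)
  wr("", 44)
  wr(as.character(n_records), 8)
  wr("1", 8)
  wr(as.character(nch), 4)
  for (nm in eeg$channel_names) wr(nm, 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(fmt_num(-pmax[i]), 8)
  for (i in seq_len(nch)) wr(fmt_num(pmax[i]), 8)
  for (i in seq_len(nch)) wr("-32767", 8)
  for (i in seq_len(nch)) wr("32767", 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(as.character(srate), 8)
  for (i in seq_len(nch)) wr("", 32)

  dig <- round(sweep(data, 1, scale, "/"))
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * srate + 1L):(r * srate)
    block <- t(dig[, cols, drop = FALSE])    # samples x channels
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}
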