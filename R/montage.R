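# Electrode montages on the unit sphere.

#' Construct an electrode montage
#'
#' A montage is a set of uniquely named electrodes with 3-D positions on the
#' unit sphere (the head is modelled as a unit sphere; +x right, +y nose,
#' +z vertex).
#'
#' @param names character vector of unique electrode labels (10-20 style).
#' @param positions numeric matrix, one row per electrode, columns x, y, z;
#'   every row must have Euclidean norm 1 within 1e-6.
#' @return an object of class `eeg_montage` with elements `names` and
#'   `positions`.
#' @export
electrode_montage <- function(names, positions) {
  names <- as.character(names)
  positions <- as.matrix(positions)
  if (anyDuplicated(names))
    abort("electrode names must be unique", "icaclean_montage_error")
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    abort("positions must be a length(names) x 3 matrix",
          "icaclean_montage_error")
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6))
    abort("electrode positions must lie on the unit sphere (|pos| = 1)",
          "icaclean_montage_error")
  rownames(positions) <- names
  structure(list(names = names, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " electrodes: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Idealised spherical angles for the 32-channel 10-20 layout.
# Convention: `incl` = inclination from the vertex in degrees, sign gives the
# hemisphere (negative left); `rot` rotates from the ear axis towards the
# nose (front positive on the right, negative on the left).
.std32_table <- function() {
  data.frame(
    name = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
             "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
             "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
             "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"),
    incl = c(-92, -74, -92, -60, -32, -72, -92, -46,
             -32, -72, -92, -60, 46, -74, -92, 92,
             92, 74, 60, 92, 72, 32, 46, 92,
             72, 32, 60, 92, 74, 92, 46, 0),
    rot = c(-72, -65, -36, -51, -45, -21, 0, 0,
            45, 21, 36, 51, -90, 65, 72, -90,
            -72, -65, -51, -36, -21, -45, 0, 0,
            21, 45, 51, 36, 65, 72, 90, 0),
    stringsAsFactors = FALSE
  )
}

#' Standard 32-channel 10-20 montage
#'
#' Idealised unit-sphere positions for the 32-electrode 10-20 layout used by
#' common 32-channel amplifiers.
#'
#' @return an `eeg_montage` with 32 electrodes.
#' @export
standard_montage_32 <- function() {
  tb <- .std32_table()
  inc <- abs(tb$incl) * pi / 180
  az <- ifelse(tb$incl >= 0, tb$rot, 180 + tb$rot) * pi / 180
  pos <- cbind(
    x = sin(inc) * cos(az),
    y = sin(inc) * sin(az),
    z = cos(inc)
  )
  pos[tb$incl == 0, ] <- c(0, 0, 1)
  electrode_montage(tb$name, pos)
}

# Great-circle (angular) distance matrix between electrode positions.
montage_angles <- function(montage) {
  cosg <- tcrossprod(montage$positions)
  cosg[cosg > 1] <- 1
  cosg[cosg < -1] <- -1
  acos(cosg)
}
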