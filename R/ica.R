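# ICA decomposition container, sign/scale normalisation, a deterministic
# FastICA implementation, and lossless component removal.

#' Construct an ICA decomposition
#'
#' On construction the decomposition is normalised to the package's
#' sign/scale convention: every mixing column has unit Euclidean norm and
#' its largest-magnitude entry is positive, with the source rows rescaled so
#' the product `mixing %*% sources` is preserved.
#'
#' @param mixing channels x components matrix (scalp pattern per column).
#' @param sources components x samples matrix of source time courses.
#' @param srate sampling rate, Hz.
#' @param montage_ref montage identifier.
#' @param center optional per-channel mean that was removed before
#'   unmixing; added back on reconstruction.
#' @return an object of class `eeg_ica`.
#' @export
ica_decomposition <- function(mixing, sources, srate,
                              montage_ref = "std32", center = NULL) {
  mixing <- as.matrix(mixing)
  sources <- as.matrix(sources)
  if (ncol(mixing) != nrow(sources))
    abort("mixing columns must match source rows", "icaclean_ica_error")
  if (ncol(mixing) > nrow(mixing))
    abort("cannot have more components than channels",
          "icaclean_ica_error")
  if (is.null(center)) center <- numeric(nrow(mixing))
  obj <- structure(list(mixing = mixing, sources = sources, srate = srate,
                        montage_ref = montage_ref, center = center),
                   class = "eeg_ica")
  normalize_ica(obj)
}

#' Apply the sign/scale convention to an ICA decomposition
#'
#' @param ica an `eeg_ica`.
#' @return the normalised `eeg_ica`; `mixing %*% sources` is unchanged up
#'   to numerical precision.
#' @export
normalize_ica <- function(ica) {
  A <- ica$mixing
  S <- ica$sources
  for (k in seq_len(ncol(A))) {
    nrm <- sqrt(sum(A[, k]^2))
    if (nrm == 0) next
    sgn <- sign(A[which.max(abs(A[, k])), k])
    if (sgn == 0) sgn <- 1
    A[, k] <- A[, k] / (nrm * sgn)
    S[k, ] <- S[k, ] * (nrm * sgn)
  }
  ica$mixing <- A
  ica$sources <- S
  ica
}

#' @export
print.eeg_ica <- function(x, ...) {
  cat(sprintf("<eeg_ica> %d components, %d channels, %d samples @ %g Hz\n",
              ncol(x$mixing), nrow(x$mixing), ncol(x$sources), x$srate))
  invisible(x)
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300))) %*% W
}

#' Independent component analysis of a preprocessed recording
#'
#' Deterministic symmetric FastICA (log-cosh contrast, identity
#' initialisation) restricted to the numerical rank of the data, so
#' interpolated channels and average referencing yield fewer components
#' than channels. Rejected samples are excluded from the fit; source time
#' courses are computed for the full recording.
#'
#' @param eeg an [continuous_eeg()] object (preprocessed).
#' @param max_iter maximum FastICA iterations.
#' @param tol convergence tolerance on the update angle.
#' @param rank_tol relative eigenvalue tolerance for the rank decision.
#' @return an [ica_decomposition()].
#' @export
run_ica <- function(eeg, max_iter = 200, tol = 1e-6, rank_tol = 1e-9) {
  X <- retained_data(eeg)
  nch <- nrow(X)
  if (ncol(X) < 20 * nch^2)
    abort(sprintf("insufficient data for ICA: need >= %d retained samples (20 x channels^2), have %d",
                  20 * nch^2, ncol(X)), "icaclean_data_sufficiency_error")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  r <- sum(eg$values > max(eg$values) * rank_tol)
  U <- eg$vectors[, seq_len(r), drop = FALSE]
  d <- sqrt(eg$values[seq_len(r)])
  K <- t(U) / d                      # whitening (r x nch)
  Z <- K %*% Xc                      # r x T, identity covariance
  Tn <- ncol(Z)

  W <- diag(r)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / Tn - gp * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }

  A <- U %*% (d * t(W))              # dewhitened mixing (nch x r)
  Sfull <- (W %*% K) %*% (eeg$data - ctr)
  ica_decomposition(A, Sfull, eeg$srate, eeg$montage_ref, center = ctr)
}

#' Reconstruct channel data from an ICA decomposition
#'
#' @param ica an `eeg_ica`.
#' @param keep optional logical/integer selection of components to include
#'   (default: all).
#' @return channels x samples matrix.
#' @export
reconstruct_eeg <- function(ica, keep = NULL) {
  A <- ica$mixing
  if (!is.null(keep)) {
    drop_mask <- rep(TRUE, ncol(A))
    drop_mask[keep] <- FALSE
    A[, drop_mask] <- 0
  }
  A %*% ica$sources + ica$center
}

#' Remove artifact components losslessly
#'
#' Zeroes the mixing columns labelled `+1` (artifact) and re-projects, so
#' the output has the same duration and channel count as the input to ICA.
#'
#' @param ica an `eeg_ica`.
#' @param artifact_labels a [label_set()] (or +1/-1 vector), one label per
#'   component; `+1` marks components to remove.
#' @param channel_names channel names for the output (defaults to
#'   `rownames(ica$mixing)` or generated names).
#' @return an [continuous_eeg()] with the artifact components removed.
#' @export
remove_components <- function(ica, artifact_labels, channel_names = NULL) {
  lab <- as_label_vector(artifact_labels)
  if (length(lab) != ncol(ica$mixing))
    abort("labels length must equal the number of components",
          "icaclean_input_error")
  keep <- which(lab == -1L)
  data <- reconstruct_eeg(ica, keep = keep)
  if (is.null(channel_names))
    channel_names <- rownames(ica$mixing) %||%
      paste0("ch", seq_len(nrow(ica$mixing)))
  continuous_eeg(data, ica$srate, channel_names, ica$montage_ref)
}
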