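# Shared fixture builders; everything is generated in code at test time.

std32 <- standard_montage_32()

# Smooth band-limited multichannel field: spatial modes up to degree 2,
# temporal content below ~15 Hz, plus per-channel white sensor noise.
smooth_field_eeg <- function(seed, dur_s = 20, srate = 512,
                             noise_sd = 0.03) {
  pos <- std32$positions
  B <- cbind(pos[, 1], pos[, 2], pos[, 3], pos[, 1] * pos[, 2],
             (3 * pos[, 3]^2 - 1) / 2)
  n <- dur_s * srate
  lp <- design_fir("lowpass", 12, 15, srate)
  set.seed(seed)
  coef <- t(sapply(1:5, function(i)
    icaclean:::fir_pass(icaclean:::pink_noise(n, 1, srate), lp$h)))
  X <- B %*% coef + noise_sd * matrix(rnorm(32 * n), 32)
  continuous_eeg(X, srate, std32$names)
}

# A one-component decomposition around a given (pattern, source) pair.
single_component_ica <- function(pattern, source, srate = 512) {
  ica_decomposition(matrix(pattern, ncol = 1), matrix(source, nrow = 1),
                    srate)
}

# Two-class Gaussian feature clouds in 6-D for classifier tests.
gaussian_clouds <- function(n_per_class, sep = 2, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 6), ncol = 6),
             matrix(rnorm(n_per_class * 6), ncol = 6))
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + sep
  X[n_per_class + seq_len(n_per_class), 1] <-
    X[n_per_class + seq_len(n_per_class), 1] - sep
  colnames(X) <- c("current_density_norm", "range_within_pattern",
                   "mean_local_skewness", "lambda", "fit_error",
                   "alpha_band_power")
  list(features = as.data.frame(X),
       labels = rep(c(1L, -1L), each = n_per_class))
}
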