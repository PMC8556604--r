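test_that("current density norm separates focal from dipolar patterns", {
  focal <- rep(1e-6, 32); focal[5] <- 1
  dip <- icaclean:::with_local_seed(3, icaclean:::dipolar_map(std32))
  v_focal <- feat_current_density_norm(focal, std32)
  v_dip <- feat_current_density_norm(dip, std32)
  expect_gt(v_focal, v_dip)
  # invariant to pattern scale
  expect_equal(feat_current_density_norm(3 * focal, std32), v_focal)
  # equivariant under a consistent permutation of electrodes/positions
  perm <- icaclean:::with_local_seed(4, sample(32))
  mont_p <- electrode_montage(std32$names[perm], std32$positions[perm, ])
  expect_equal(feat_current_density_norm(focal[perm], mont_p), v_focal,
               tolerance = 1e-8)
  expect_error(feat_current_density_norm(rep(1, 10), std32),
               class = "icaclean_dimension_error")
})

test_that("pattern range feature is the log peak-to-peak value", {
  p1 <- c(0.8, -0.2, rep(0.1, 30))
  expect_equal(feat_range_within_pattern(p1), 0)
  p2 <- c(0.5, -0.5, rep(0, 30))
  expect_equal(feat_range_within_pattern(p2), 0)
  expect_equal(feat_range_within_pattern(p1 + 5),
               feat_range_within_pattern(p1))
  expect_error(feat_range_within_pattern(rep(2, 32)),
               class = "icaclean_degenerate_pattern_error")
})

test_that("mean local skewness is low for noise, high for blinks", {
  srate <- 512
  set.seed(3)
  gauss <- rnorm(120 * srate)
  expect_lt(feat_mean_local_skewness(gauss, srate), 0.2)

  # one large positive 0.3-s pulse per 15-s window
  blink <- gauss * 0.5
  for (k in 0:7) {
    idx <- k * 15 * srate + 2 * srate + seq_len(round(0.3 * srate))
    blink[idx] <- blink[idx] + 8
  }
  v <- feat_mean_local_skewness(blink, srate)
  expect_gt(v, 1.0)
  expect_equal(feat_mean_local_skewness(-blink, srate), v)
  expect_error(feat_mean_local_skewness(rnorm(100), srate),
               class = "icaclean_length_error")
})

test_that("Welch spectrum localises oscillations and scales correctly", {
  srate <- 512; n <- 60 * srate
  set.seed(9)
  src <- sin(2 * pi * 7.5 * seq_len(n) / srate) + 0.05 * rnorm(n)
  sp <- estimate_spectrum(src, srate)
  expect_equal(sp$freqs_hz[which.max(sp$log_power)], 7.5, tolerance = 0.25)

  wn <- rnorm(n)
  spw <- estimate_spectrum(wn, srate)
  band <- spw$freqs_hz >= 2 & spw$freqs_hz <= 20
  expect_lt(diff(range(10 * spw$log_power[band] / log(10))), 2)  # dB

  sp2 <- estimate_spectrum(2 * wn, srate)
  expect_equal(sp2$log_power - spw$log_power,
               rep(log(4), length(spw$log_power)), tolerance = 1e-9)
  expect_error(estimate_spectrum(wn, srate, fit_band_hz = c(2, 300)),
               class = "icaclean_parameter_error")
})

test_that("1/f fit recovers the exponent and flags alpha bumps", {
  freqs <- seq(2, 20, by = 0.5)
  spec_exact <- structure(list(freqs_hz = freqs,
                               log_power = log(3 / freqs^2),
                               fit_band_hz = c(2, 20)),
                          class = "spectral_estimate")
  fit <- feat_spectral_fit(spec_exact)
  expect_equal(fit[["lambda"]], 2, tolerance = 1e-6)
  expect_lte(fit[["fit_error"]], 1e-10)

  set.seed(13)
  wn <- estimate_spectrum(rnorm(512 * 60), 512)
  expect_equal(feat_spectral_fit(wn)[["lambda"]], 0, tolerance = 0.05)

  bump <- spec_exact
  bump$log_power <- bump$log_power + 3 * exp(-(freqs - 7.5)^2 / 0.5)
  expect_gt(feat_spectral_fit(bump)[["fit_error"]], fit[["fit_error"]])
  narrow <- structure(list(freqs_hz = freqs[1:4],
                           log_power = log(3 / freqs[1:4]^2),
                           fit_band_hz = c(2, 3)),
                      class = "spectral_estimate")
  expect_error(feat_spectral_fit(narrow),
               class = "icaclean_parameter_error")
})

test_that("alpha-band power follows band placement", {
  srate <- 512; n <- 60 * srate
  set.seed(14)
  osc <- sin(2 * pi * 7.5 * seq_len(n) / srate) + 0.05 * rnorm(n)
  sp <- estimate_spectrum(osc, srate)
  wh <- estimate_spectrum(rnorm(n) * sd(osc), srate)
  expect_gt(feat_alpha_power(sp, c(6, 9)) - feat_alpha_power(wh, c(6, 9)), 3)
  # the 7.5 Hz source scores higher in infant mode than in adult mode
  expect_gt(feat_alpha_power(sp, c(6, 9)), feat_alpha_power(sp, c(8, 13)))
  flat <- structure(list(freqs_hz = seq(0, 20, 0.5),
                         log_power = rep(1.7, 41), fit_band_hz = c(2, 20)),
                    class = "spectral_estimate")
  expect_equal(feat_alpha_power(flat, c(6, 9)), 1.7)
  expect_error(feat_alpha_power(sp, c(6.1, 6.4)),
               class = "icaclean_parameter_error")
})

test_that("extract_features is invariant to component rescaling and sign", {
  spec <- synthetic_spec(duration_s = 60)
  cmp_b <- make_component("blink", spec, seed = 2)
  cmp_n <- make_component("neural_alpha", spec, seed = 3)
  A <- cbind(cmp_b$pattern, cmp_n$pattern)
  S <- rbind(cmp_b$source, cmp_n$source)
  ica <- ica_decomposition(A, S, spec$srate)
  ft <- extract_features(ica, std32, "infant")

  cs <- c(3.7, 0.2)
  ica2 <- ica_decomposition(sweep(A, 2, cs, "*") %*% diag(c(-1, 1)),
                            diag(c(-1, 1)) %*% sweep(S, 1, cs, "/"),
                            spec$srate)
  ft2 <- extract_features(ica2, std32, "infant")
  expect_equal(as.matrix(ft2[, icaclean:::.feature_cols]),
               as.matrix(ft[, icaclean:::.feature_cols]),
               tolerance = 1e-8)

  # determinism: identical inputs give bit-identical TSV output
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_feature_table(extract_features(ica, std32, "infant"), p1)
  write_feature_table(extract_features(ica, std32, "infant"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("infant mode reads nothing above 20 Hz", {
  spec <- synthetic_spec(duration_s = 60)
  cmp <- make_component("neural_broadband", spec, seed = 5)
  n <- length(cmp$source)
  hi <- sin(2 * pi * 30 * seq_len(n) / spec$srate)
  ica_a <- single_component_ica(cmp$pattern, cmp$source)
  ica_b <- single_component_ica(cmp$pattern, cmp$source + 0.5 * hi)
  fa <- extract_features(ica_a, std32, "infant")
  fb <- extract_features(ica_b, std32, "infant")
  # spectral features ignore the 30 Hz content entirely (up to the tiny
  # change in overall source variance used for normalisation)
  expect_equal(fb$lambda, fa$lambda, tolerance = 0.02)
  expect_equal(fb$alpha_band_power - fa$alpha_band_power,
               log(var(cmp$source) / var(cmp$source + 0.5 * hi)),
               tolerance = 0.02)
})
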