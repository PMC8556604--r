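test_that("montage electrodes lie on the unit sphere with unique names", {
  expect_equal(unname(sqrt(rowSums(std32$positions^2))), rep(1, 32),
               tolerance = 1e-9)
  expect_false(anyDuplicated(std32$names) > 0)
  expect_error(electrode_montage(c("a", "a"), diag(2) %x% c(1, 0, 0)),
               class = "icaclean_montage_error")
})

test_that("ICA normalisation fixes sign and scale and preserves the product", {
  set.seed(1)
  A <- matrix(rnorm(32 * 4), 32)
  S <- matrix(rnorm(4 * 1000), 4)
  ica <- ica_decomposition(A, S, 512)
  expect_equal(unname(sqrt(colSums(ica$mixing^2))), rep(1, 4),
               tolerance = 1e-12)
  for (k in 1:4)
    expect_gt(ica$mixing[which.max(abs(ica$mixing[, k])), k], 0)
  expect_lt(icaclean:::rel_error(reconstruct_eeg(ica), A %*% S), 1e-12)

  # rescaling columns by c > 0 and rows by 1/c gives the identical
  # normalised form
  cs <- runif(4, 0.2, 5)
  ica2 <- ica_decomposition(sweep(A, 2, cs, "*"), sweep(S, 1, cs, "/"), 512)
  expect_equal(ica2$mixing, ica$mixing, tolerance = 1e-10)
  expect_equal(ica2$sources, ica$sources, tolerance = 1e-10)
})

test_that("label sets accept only +1/-1", {
  expect_silent(label_set(c(1, -1, 1)))
  expect_error(label_set(c(1, 0)), class = "icaclean_label_error")
  expect_error(label_set(integer(0)), class = "icaclean_label_error")
})

test_that("EDF write/read round trip is exact to the quantisation step", {
  set.seed(2)
  dur <- 10; srate <- 512
  X <- rbind(50 * sin(2 * pi * 7 * seq_len(dur * srate) / srate),
             20 * icaclean:::pink_noise(dur * srate, 1, srate),
             rnorm(dur * srate))
  eeg <- continuous_eeg(X, srate, c("Fp1", "Cz", "O2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_continuous_eeg(eeg, path)
  back <- read_continuous_eeg(path)
  expect_equal(dim(back$data), dim(eeg$data))
  expect_equal(back$srate, srate)
  expect_equal(back$channel_names, eeg$channel_names)
  qstep <- apply(abs(X), 1, max) * 1.0001 / 32767
  for (i in 1:3)
    expect_lt(max(abs(back$data[i, ] - X[i, ])), qstep[i] * 1.01)
})

test_that("trigger channels are excluded and reported on read", {
  set.seed(3)
  X <- rbind(rnorm(5120), rnorm(5120), round(runif(5120, 0, 7)))
  eeg <- continuous_eeg(X, 512, c("Fp1", "Oz", "Status"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_continuous_eeg(eeg, path)
  back <- read_continuous_eeg(path)
  expect_equal(nrow(back$data), 2L)
  expect_equal(attr(back, "excluded_channels"), "Status")
})

test_that("BDF files (24-bit) read with correct gain", {
  # hand-assemble a tiny 2-channel BDF: 1 record, 4 samples/record
  path <- withr::local_tempfile(fileext = ".bdf")
  con <- file(path, "wb")
  pad <- function(s, w) writeChar(formatC(s, width = -w), con, w, eos = NULL)
  writeBin(as.raw(0xff), con); pad("BIOSEMI", 7)
  pad("", 80); pad("", 80); pad("01.01.26", 8); pad("00.00.00", 8)
  pad("768", 8); pad("24BIT", 44); pad("1", 8); pad("1", 8); pad("2", 4)
  pad("Fp1", 16); pad("Cz", 16)
  for (i in 1:2) pad("", 80)
  for (i in 1:2) pad("uV", 8)
  for (i in 1:2) pad("-1000", 8)
  for (i in 1:2) pad("1000", 8)
  for (i in 1:2) pad("-1000", 8)
  for (i in 1:2) pad("1000", 8)
  for (i in 1:2) pad("", 80)
  for (i in 1:2) pad("4", 8)
  for (i in 1:2) pad("", 32)
  vals <- c(0L, 100L, -100L, 500L, 1L, 2L, 3L, -4L)   # digital == physical
  for (v in vals) {
    u <- if (v < 0) v + 16777216L else v
    writeBin(as.raw(c(u %% 256, (u %/% 256) %% 256, u %/% 65536)), con)
  }
  close(con)
  eeg <- read_continuous_eeg(path)
  expect_equal(eeg$data[1, ], c(0, 100, -100, 500))
  expect_equal(eeg$data[2, ], c(1, 2, 3, -4))
  expect_equal(eeg$srate, 4)
})

test_that("feature tables round-trip through TSV", {
  set.seed(4)
  ft <- data.frame(current_density_norm = rnorm(3),
                   range_within_pattern = rnorm(3),
                   mean_local_skewness = abs(rnorm(3)),
                   lambda = rnorm(3), fit_error = abs(rnorm(3)),
                   alpha_band_power = rnorm(3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  expect_length(readLines(path), 4L)               # header + 3 rows
  back <- read_feature_table(path)
  expect_equal(as.matrix(back[, names(ft)]), as.matrix(ft),
               tolerance = 1e-6)

  write_feature_table(ft, path, labels = label_set(c(1, -1, 1)))
  back2 <- read_feature_table(path)
  expect_true(all(back2$label %in% c(-1L, 1L)))
  expect_equal(back2$label, c(1L, -1L, 1L))
  expect_error(write_feature_table(ft[0, ], path),
               class = "icaclean_io_error")
})

test_that("classifier JSON serialisation round-trips exactly", {
  clouds <- gaussian_clouds(30)
  clf <- train_component_classifier(clouds$features, clouds$labels,
                                    alpha_band = c(6, 9))
  path <- withr::local_tempfile(fileext = ".json")
  serialize_classifier(clf, path)
  back <- deserialize_classifier(path)
  for (f in c("w", "b", "feature_means", "feature_sds", "alpha_band"))
    expect_identical(format(unname(back[[f]]), digits = 17),
                     format(unname(clf[[f]]), digits = 17))
  expect_equal(back$alpha_band, c(6, 9))           # infant mode recorded

  # a file missing alpha_band is rejected with the field named
  obj <- jsonlite::read_json(path)
  obj$alpha_band <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(deserialize_classifier(path), "alpha_band",
               class = "icaclean_schema_error")
})
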