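# Seeded generator of labelled synthetic ICA components and recordings.
#
# Components emulate the classes an infant-EEG classifier must separate:
# neural sources with 1/f spectra (and an infant alpha peak drawn from
# 6-9 Hz), plus blink, lateral eye movement, muscle and single-electrode
# "pop" artifacts. Scalp maps of neural sources come from the same
# three-shell spherical forward model used by the current-density feature;
# artifact maps are idealised frontal/focal weightings on the unit sphere.

.synth_classes <- c("neural_alpha", "neural_broadband", "blink",
                    "lateral_eye", "muscle", "channel_pop")

#' Synthetic-data specification
#'
#' @param srate sampling rate, Hz.
#' @param duration_s component/recording duration, seconds.
#' @param montage electrode montage (default the 32-channel 10-20 layout).
#' @param class_mix named proportions over the six component classes
#'   (must sum to 1).
#' @param mode `"infant"` (alpha peak drawn uniformly from 6-9 Hz) or
#'   `"adult"` (9-13 Hz).
#' @param snr amplitude ratio of projected sources to sensor noise in
#'   [make_recording()].
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(srate = 512, duration_s = 120,
                           montage = standard_montage_32(),
                           class_mix = c(neural_alpha = 0.30,
                                         neural_broadband = 0.20,
                                         blink = 0.15,
                                         lateral_eye = 0.10,
                                         muscle = 0.15,
                                         channel_pop = 0.10),
                           mode = c("infant", "adult"),
                           snr = 3) {
  mode <- match.arg(mode)
  if (abs(sum(class_mix) - 1) > 1e-8)
    abort("class_mix proportions must sum to 1",
          "icaclean_parameter_error")
  if (!all(names(class_mix) %in% .synth_classes))
    abort("unknown class in class_mix", "icaclean_parameter_error")
  structure(list(srate = srate, duration_s = duration_s, montage = montage,
                 class_mix = class_mix, mode = mode, snr = snr),
            class = "synthetic_spec")
}

# 1/f^lambda noise via FFT shaping, unit variance.
pink_noise <- function(n, lambda, srate) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * srate / n
  H <- c(0, f[-1]^(-lambda / 2))
  x <- Re(stats::fft(W * H, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Noise with power rising towards high frequencies (muscle-like).
rising_noise <- function(n, srate, knee_hz = 15) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * srate / n
  H <- f / sqrt(f^2 + knee_hz^2) * (f / srate)^0.25
  H[1] <- 0
  x <- Re(stats::fft(W * H, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Gaussian weighting of electrodes around a target direction.
gaussian_map <- function(montage, target, sigma) {
  target <- target / sqrt(sum(target^2))
  ang <- acos(pmin(pmax(montage$positions %*% target, -1), 1))
  w <- exp(-ang^2 / (2 * sigma^2))
  as.numeric(w)
}

# Direction on the unit sphere given inclination-from-vertex and azimuth
# (degrees; azimuth 90 = nose, 0 = right ear), with uniform jitter so no
# two generated artifact maps are exactly collinear.
jittered_direction <- function(incl_deg, azim_deg, jitter_deg = 8) {
  incl <- (incl_deg + stats::runif(1, -jitter_deg, jitter_deg)) * pi / 180
  azim <- (azim_deg + stats::runif(1, -jitter_deg, jitter_deg)) * pi / 180
  c(sin(incl) * cos(azim), sin(incl) * sin(azim), cos(incl))
}

# Smooth dipolar map: random dipole through the spherical head model.
dipolar_map <- function(montage, toward = NULL) {
  lf <- compute_leadfield_cached(montage)
  nd <- nrow(lf$dipoles)
  if (is.null(toward)) {
    k <- sample.int(nd, 1)
  } else {
    toward <- toward / sqrt(sum(toward^2))
    sc <- lf$dipoles %*% toward
    k <- order(-sc)[sample.int(10, 1)]      # near the requested direction
  }
  ori <- stats::rnorm(3)
  ori <- ori / sqrt(sum(ori^2))
  cols <- (k - 1L) * 3L + 1:3
  p <- lf$L[, cols] %*% ori
  as.numeric(p)
}

compute_leadfield_cached <- function(montage) {
  key <- paste0("lf|", paste(montage$names, collapse = "|"))
  if (is.null(.lf_cache[[key]]))
    .lf_cache[[key]] <- compute_leadfield(montage)
  .lf_cache[[key]]
}

# Positive pulse train (blink-like): one pulse roughly every 1.5-4 s.
pulse_train <- function(n, srate, amp_range = c(4, 8),
                        width_range = c(0.2, 0.4)) {
  x <- numeric(n)
  t <- stats::runif(1, 0.5, 2) * srate
  while (t < n) {
    w <- as.integer(round(stats::runif(1, width_range[1], width_range[2]) *
                            srate))
    a <- stats::runif(1, amp_range[1], amp_range[2])
    idx <- as.integer(round(t)) + seq_len(w)
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + a * (0.5 - 0.5 * cos(2 * pi * seq_along(idx) / w))
    t <- t + stats::runif(1, 1.5, 4) * srate
  }
  x
}

# Step-like transients (lateral eye movements): alternating gaze levels
# with 50 ms raised-cosine edges.
step_train <- function(n, srate) {
  x <- numeric(n)
  pos <- 1L
  level <- 0
  while (pos < n) {
    seg <- as.integer(round(stats::runif(1, 0.8, 3) * srate))
    new_level <- sample(c(-1, 0, 1), 1) * stats::runif(1, 0.8, 1.2)
    edge <- as.integer(round(0.05 * srate))
    idx <- pos:min(pos + seg - 1L, n)
    ramp <- pmin(seq_along(idx) / edge, 1)
    x[idx] <- level + (new_level - level) *
      (0.5 - 0.5 * cos(pi * pmin(ramp, 1)))
    level <- new_level
    pos <- pos + seg
  }
  x
}

# Heavy-tailed pops: pink background plus sporadic large offsets.
pop_source <- function(n, srate) {
  x <- pink_noise(n, 0.5, srate)
  t <- stats::runif(1, 1, 5) * srate
  while (t < n) {
    dur <- as.integer(round(stats::runif(1, 0.2, 1) * srate))
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 5, 15)
    idx <- as.integer(round(t)) + seq_len(dur)
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + amp
    t <- t + stats::runif(1, 3, 8) * srate
  }
  x
}

#' Generate one labelled synthetic component
#'
#' @param class one of `"neural_alpha"`, `"neural_broadband"`, `"blink"`,
#'   `"lateral_eye"`, `"muscle"`, `"channel_pop"`.
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; output is fully determined by
#'   `(class, spec, seed)`.
#' @return list with `pattern` (unit-norm scalp map), `source` (time
#'   course), and `label` (+1 artifact / -1 neural).
#' @export
make_component <- function(class, spec = synthetic_spec(), seed = 1) {
  if (!class %in% .synth_classes)
    abort(paste0("unknown component class: ", class),
          "icaclean_parameter_error")
  n <- as.integer(round(spec$duration_s * spec$srate))
  mont <- spec$montage
  alpha_range <- if (spec$mode == "infant") c(6, 9) else c(9, 13)
  with_local_seed(seed, {
    out <- switch(
      class,
      neural_alpha = {
        lam <- stats::runif(1, 0.8, 1.6)
        f <- stats::runif(1, alpha_range[1], alpha_range[2])
        a <- stats::runif(1, 1.0, 2.0)
        src <- pink_noise(n, lam, spec$srate) +
          a * sin(2 * pi * f * seq_len(n) / spec$srate +
                    stats::runif(1, 0, 2 * pi))
        list(pattern = dipolar_map(mont), source = src, label = -1L)
      },
      neural_broadband = {
        lam <- stats::runif(1, 0.8, 1.6)
        list(pattern = dipolar_map(mont),
             source = pink_noise(n, lam, spec$srate), label = -1L)
      },
      blink = {
        src <- 0.3 * pink_noise(n, 1, spec$srate) +
          pulse_train(n, spec$srate)
        front <- gaussian_map(mont, jittered_direction(80, 90),
                              stats::runif(1, 0.35, 0.55))
        list(pattern = front, source = src, label = 1L)
      },
      lateral_eye = {
        src <- 0.25 * pink_noise(n, 1, spec$srate) +
          step_train(n, spec$srate)
        sg <- stats::runif(1, 0.3, 0.5)
        lft <- gaussian_map(mont, jittered_direction(75, 120, 5), sg)
        rgt <- gaussian_map(mont, jittered_direction(75, 60, 5), sg)
        list(pattern = lft - rgt, source = src, label = 1L)
      },
      muscle = {
        side <- sample(c(0, 180), 1)       # right or left temporal rim
        edge <- gaussian_map(mont, jittered_direction(85, side),
                             stats::runif(1, 0.25, 0.45))
        list(pattern = edge, source = rising_noise(n, spec$srate),
             label = 1L)
      },
      channel_pop = {
        ch <- sample.int(length(mont$names), 1)
        pat <- 0.05 * gaussian_map(mont, mont$positions[ch, ], 1.0)
        pat[ch] <- pat[ch] + 1
        list(pattern = pat, source = pop_source(n, spec$srate),
             label = 1L)
      }
    )
    out$pattern <- out$pattern / sqrt(sum(out$pattern^2))
    out$class <- class
    out
  })
}

#' Generate a labelled corpus of synthetic components with features
#'
#' Draws component classes according to `spec$class_mix` (largest-remainder
#' rounding, shuffled order), builds each component, and computes the six
#' features via [extract_features()] on single-component decompositions.
#'
#' Real training corpora consist of ICA *estimates*, which are never pure:
#' each estimated component carries a varying admixture of other sources,
#' mostly small but occasionally substantial. The generator emulates this
#' by blending each component's unit-variance source with a random
#' fraction (`mix_max * Beta(1, 2)`, so admixture is usually mild with a
#' decreasing tail) of an independent 1/f background, and perturbing its
#' scalp map proportionally, with the label kept from the dominant part.
#'
#' @param n_components number of components (>= 20).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @param mix_max maximal admixture fraction (amplitude) of background
#'   source activity per component (default 0.7).
#' @return list with `features` (data.frame incl. `class` column), and
#'   `labels` (a [label_set()]).
#' @export
make_labelled_corpus <- function(n_components, spec = synthetic_spec(),
                                 seed = 1, mix_max = 0.7) {
  if (n_components < 20)
    abort("corpus needs at least 20 components",
          "icaclean_parameter_error")
  mix <- spec$class_mix
  base <- floor(mix * n_components)
  rem <- n_components - sum(base)
  if (rem > 0) {
    extra <- order(-(mix * n_components - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  classes <- rep(names(mix), times = base)
  info <- with_local_seed(seed, {
    classes <- sample(classes)
    comp_seeds <- sample.int(.Machine$integer.max - 1L, n_components)
    blend_seeds <- sample.int(.Machine$integer.max - 1L, n_components)
    list(classes = classes, comp_seeds = comp_seeds,
         blend_seeds = blend_seeds)
  })
  n <- as.integer(round(spec$duration_s * spec$srate))
  rows <- vector("list", n_components)
  labels <- integer(n_components)
  for (i in seq_len(n_components)) {
    cmp <- make_component(info$classes[i], spec, info$comp_seeds[i])
    cmp <- with_local_seed(info$blend_seeds[i], {
      m <- mix_max * stats::rbeta(1, 1, 2)
      bg <- pink_noise(n, stats::runif(1, 0.8, 1.6), spec$srate)
      src <- cmp$source / stats::sd(cmp$source)
      cmp$source <- (1 - m) * src + m * bg
      bp <- dipolar_map(spec$montage)
      bp <- bp / sqrt(sum(bp^2))
      pat <- (1 - 0.5 * m) * cmp$pattern + 0.5 * m * bp
      cmp$pattern <- pat / sqrt(sum(pat^2))
      cmp
    })
    ica <- ica_decomposition(matrix(cmp$pattern, ncol = 1),
                             matrix(cmp$source, nrow = 1), spec$srate)
    ft <- extract_features(ica, spec$montage, spec$mode)
    ft$component_id <- i
    ft$class <- info$classes[i]
    rows[[i]] <- ft
    labels[i] <- cmp$label
  }
  features <- do.call(rbind, rows)
  list(features = features, labels = label_set(labels, "manual"))
}

#' Generate a synthetic multichannel recording
#'
#' Sums forward-projected components plus spatially correlated pink sensor
#' noise. With an ERP scene, saccade-locked frontal transients (peaking
#' near the fixation onset) and fixation-locked occipital responses
#' (peaking 200-300 ms later) are inserted at the event times.
#'
#' @param spec a [synthetic_spec()] (duration >= 30 s).
#' @param seed integer seed.
#' @param erp_scene `NULL`, or a list with `n_events` (default 40),
#'   `artifact_amp` (default 6) and `response_amp` (default 1.5).
#' @param n_background number of background components (default 10).
#' @return list with `eeg` (an [continuous_eeg()]), `components` (the
#'   ground-truth patterns/sources/labels), `events` (data.frame of
#'   fixation-onset latencies; zero rows without a scene), and
#'   `noise` (the sensor-noise matrix).
#' @export
make_recording <- function(spec = synthetic_spec(), seed = 1,
                           erp_scene = NULL, n_background = 10) {
  if (spec$duration_s < 30)
    abort("recording must be at least 30 s", "icaclean_parameter_error")
  n <- as.integer(round(spec$duration_s * spec$srate))
  mont <- spec$montage
  nch <- length(mont$names)

  plan <- with_local_seed(seed, {
    classes <- sample(names(spec$class_mix), n_background, replace = TRUE,
                      prob = spec$class_mix)
    # a recording has one pair of eyes: at most one blink and one
    # lateral-eye generator; surplus draws become other classes
    for (ocular in c("blink", "lateral_eye")) {
      surplus <- which(classes == ocular)[-1]
      if (length(surplus)) {
        pool <- setdiff(names(spec$class_mix), c("blink", "lateral_eye"))
        classes[surplus] <- sample(pool, length(surplus), replace = TRUE,
                                   prob = spec$class_mix[pool])
      }
    }
    seeds <- sample.int(.Machine$integer.max - 1L, n_background + 4L)
    list(classes = classes, seeds = seeds)
  })

  comps <- vector("list", n_background)
  amp_by_class <- c(neural_alpha = 4, neural_broadband = 4, blink = 10,
                    lateral_eye = 8, muscle = 3, channel_pop = 6)
  for (i in seq_len(n_background)) {
    cmp <- make_component(plan$classes[i], spec, plan$seeds[i])
    cmp$amplitude <- unname(amp_by_class[plan$classes[i]])
    comps[[i]] <- cmp
  }

  events <- data.frame(event_id = integer(0), latency_s = numeric(0))
  if (!is.null(erp_scene)) {
    n_events <- erp_scene$n_events %||% 40L
    art_amp <- erp_scene$artifact_amp %||% 15
    rsp_amp <- erp_scene$response_amp %||% 1.5
    scene <- with_local_seed(plan$seeds[n_background + 1L], {
      span <- spec$duration_s - 6
      if (span < n_events * 2.2)
        abort("events too dense for the recording length",
              "icaclean_scene_error")
      lat <- 3 + (seq_len(n_events) - 0.5) / n_events * span +
        stats::runif(n_events, -0.3, 0.3)
      art_src <- numeric(n)
      rsp_src <- 0.4 * pink_noise(n, 1.2, spec$srate) +
        0.6 * sin(2 * pi * stats::runif(1, 6, 9) * seq_len(n) / spec$srate)
      tgrid <- seq_len(n) / spec$srate
      for (tk in lat) {
        # saccade sizes vary widely from gaze shift to gaze shift
        art_src <- art_src + stats::runif(1, 0.4, 2.0) *
          exp(-(tgrid - tk)^2 / (2 * 0.08^2))
        rsp_src <- rsp_src + stats::runif(1, 0.8, 1.2) *
          exp(-(tgrid - tk - 0.25)^2 / (2 * 0.04^2))
      }
      # ocular transients also occur away from the labelled events
      n_extra <- as.integer(round(spec$duration_s / 4))
      for (tk in stats::runif(n_extra, 1, spec$duration_s - 1))
        art_src <- art_src + stats::runif(1, 0.3, 1.5) *
          exp(-(tgrid - tk)^2 / (2 * 0.08^2))
      art_src <- art_src + 0.08 * pink_noise(n, 1, spec$srate)
      front <- gaussian_map(mont, jittered_direction(80, 90),
                            stats::runif(1, 0.35, 0.55))
      occ <- dipolar_map(mont, toward = c(0, -sin(75 * pi / 180),
                                          cos(75 * pi / 180)))
      list(lat = lat,
           artifact = list(pattern = front / sqrt(sum(front^2)),
                           source = art_src, label = 1L,
                           class = "saccade_artifact",
                           amplitude = art_amp),
           response = list(pattern = occ / sqrt(sum(occ^2)),
                           source = rsp_src, label = -1L,
                           class = "visual_response",
                           amplitude = rsp_amp))
    })
    comps <- c(comps, list(scene$artifact, scene$response))
    events <- data.frame(event_id = seq_along(scene$lat),
                         latency_s = scene$lat)
  }

  # unit-SD sources so the per-class amplitudes are scalp-RMS microvolts
  comps <- lapply(comps, function(cmp) {
    cmp$source <- cmp$source / stats::sd(cmp$source)
    cmp
  })
  signal <- matrix(0, nch, n)
  for (cmp in comps)
    signal <- signal + cmp$amplitude * (cmp$pattern %o% cmp$source)

  # sensor noise: spatially smoothed pink noise plus an iid white floor
  # (amplifier noise), keeping the noise covariance well conditioned
  noise <- with_local_seed(plan$seeds[n_background + 2L], {
    pink <- t(vapply(seq_len(nch), function(i)
      pink_noise(n, 1, spec$srate), numeric(n)))
    ang <- montage_angles(mont)
    Sm <- exp(-ang^2 / (2 * 0.5^2))
    Sm <- Sm / rowSums(Sm)
    smooth <- Sm %*% pink
    smooth / stats::sd(smooth) + 0.35 * matrix(stats::rnorm(nch * n), nch)
  })
  sig_scale <- stats::sd(as.numeric(signal))
  noise <- noise * sig_scale / (spec$snr * stats::sd(as.numeric(noise)))

  eeg <- continuous_eeg(signal + noise, spec$srate, mont$names)
  list(eeg = eeg, components = comps, events = events, noise = noise)
}
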