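---
title: "Classifying and removing artifact ICA components from infant EEG"
author: "icaclean authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and removing artifact ICA components from infant EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

EEG recorded from infants — particularly during naturalistic, free-flowing
interaction — is heavily contaminated by ocular, muscle and electrode
artifacts, and those artifacts are often time-locked to the very behaviour
under study (an infant turning to its parent produces both the gaze shift
of interest and the eye-movement artifact). Deleting contaminated segments
therefore deletes signal too. The *lossless* alternative is independent
component analysis (ICA): decompose the multichannel recording into a
mixing matrix $A$ and source time courses $S$, decide for each component
whether it is neural or artifact, zero the artifact columns of $A$, and
re-project. Recording length is preserved; only the artifact subspace is
removed.

The decision step is the bottleneck. `icaclean` automates it with a binary
linear classifier

$$H = \mathrm{sign}(w \cdot x + b) \in \{-1, +1\},$$

where $x$ is a six-dimensional feature vector describing one component,
$w$ and $b$ are learned from labelled training components, $+1$ means
*artifact* (reject) and $-1$ means *neural* (retain). A decision value of
exactly zero maps to $-1$: when in doubt, the component is kept, mirroring
how human raters are instructed to behave.

Infant EEG differs from adult EEG in exactly the properties such a
classifier consumes: the dominant posterior rhythm sits at 6–9 Hz in
one-year-olds rather than the adult 8–13 Hz, low-frequency power is
relatively larger, and scalp topographies are more bilaterally symmetric.
The package therefore exposes an `infant` mode (alpha band 6–9 Hz,
spectral fit band 2–20 Hz) and an `adult` mode (8–13 Hz, 2–40 Hz) for
feature extraction, and the classifier records at training time which band
its features came from, refusing at prediction time to mix modes.

## The six features

For each component (unit-norm scalp pattern $a$, source time course $s$):

1. **Current density norm** — $\log \lVert \hat j \rVert$ of the
   depth-weighted minimum-norm current estimate of $a$ on a fixed grid of
   642 dipoles (three Cartesian orientations each) inside a three-shell
   spherical head model (radii 0.87/0.92/1.0, conductivities
   0.33/0.0042/0.33 S/m, dipole shell at radius 0.84). Focal,
   physiologically implausible maps need large currents, so high values
   indicate artifact. The Tikhonov parameter is chosen once per montage by
   generalised cross-validation over the lead field's own columns and then
   frozen, so the feature is a deterministic function of the montage.
2. **Pattern range** — $\log(\max a - \min a)$: single-electrode
   ("pop") maps score high.
3. **Mean local skewness** — the mean over consecutive 15-s windows of the
   absolute sample skewness of $s$: blink trains of unidirectional pulses
   score high.
4. **$\lambda$** — the exponent of a $1/f^\lambda$ fit,
   $\log P(f) \approx a - \lambda \log f$, over the fit band. Muscle
   components have *rising* spectra ($\lambda < 0$); neural components
   typically sit near $\lambda \approx 1$–2.
5. **Fit error** — the mean squared residual of that fit; a clear alpha
   peak or other structured deviation raises it.
6. **Alpha band power** — mean log power over the mode's alpha band.

Spectra are Welch estimates (1-s Hamming windows, 50 % overlap, two-fold
zero padding giving a 0.5 Hz grid). Before any spectral feature is
computed the source is normalised to unit variance, so all six features
describe the *shape* of a component, not its scale; together with the
unit-norm pattern convention this makes the whole feature vector invariant
to rescaling and sign flips of a component, which tests verify to 1e-8.

## The classifier

`train_component_classifier()` z-scores the features by the training
statistics and fits regularised linear discriminant analysis: the pooled
within-class covariance is shrunk toward a scaled identity,
$\Sigma_\gamma = (1-\gamma)\Sigma + \gamma \,\bar\sigma^2 I$, with
$\gamma$ either supplied or set by the analytic (Ledoit–Wolf style)
estimator. Then $w = \Sigma_\gamma^{-1}(\mu_+ - \mu_-)$ and
$b = -w\cdot(\mu_+ + \mu_-)/2$, which places the boundary at equal
Mahalanobis distance from the class means (equal priors). LDA was chosen
because the method family this toolkit belongs to has always used a plain
binary linear classifier; it is deterministic, needs no tuning, and its
weights are interpretable feature by feature.

Agreement between two labelings is reported as the disagreement fraction
("MSE"): 0.25 means the two classifications differed on 25 % of
components. `crossvalidate()` provides seeded, stratified k-fold
estimates.

## The preprocessing pipeline

`preprocess_eeg()` runs a fixed stage order:

1. **High-pass FIR filter** — Hamming windowed-sinc, passband edge 1 Hz,
   −6 dB cutoff 0.75 Hz. The tap count follows
   $\lceil 3.3 / (tb/f_s) \rceil_{\text{even}} + 1$ with transition band
   $tb = 2\,|f_{pass} - f_{-6dB}|$; at 512 Hz this gives 3381 taps.
   Filters are applied forward–backward (zero phase).
2. **Line-noise removal** — sine/cosine regression at the line frequency
   and its first harmonic in 4-s chunks; tracks slow amplitude/phase
   drift, attenuates a stationary tone by far more than 20 dB, and removes
   only ~4 regression degrees of freedom per chunk from broadband signal.
3. **Robust average reference** — the mean over channels that survive
   bad-channel detection is subtracted from every channel.
4. **Bad-channel detection** — channel flagged if (a) its best absolute
   correlation with spherical-spline predictions of itself (eight
   deterministic predictor subsets, so one broken neighbour cannot sink a
   good channel) is below 0.7 in more than half of 1-s windows, or (b) the
   robust z of its log high-frequency noise amplitude exceeds 3. The
   robust scale is floored at 0.4 log units so that ordinary
   channel-to-channel differences (temporal muscle, say) are not flagged
   on otherwise homogeneous caps; a genuinely bad channel carries several
   times the median noise and clears the threshold easily.
5. **Spherical-spline interpolation** of flagged channels (order $m=4$,
   Legendre degree 7, ridge 1e-5), followed by restoring the average
   reference (interpolation otherwise breaks it). Interpolation of exact
   linear combinations reduces the numerical rank, and the ICA honours
   that.
6. **Low-pass FIR filter** — passband edge 20 Hz by default (40 Hz is the
   documented alternative and a config value).
7. **Gross-epoch rejection** — consecutive non-overlapping 1-s epochs; an
   epoch is marked when more than 70 % of channels exceed the grand mean
   channel power plus 5 SD. The reference distribution pools all
   epoch-by-channel powers by default (`pool_epoch_sd`), because the rule
   as usually stated is ambiguous about whether SDs are pooled; the
   per-channel variant is available via the same switch. Only whole
   epochs are removed, so retained-duration bookkeeping is exact.

`run_ica()` is a deterministic symmetric FastICA (log-cosh contrast,
identity initialisation, rank-restricted whitening). The ICA algorithm is
deliberately a replaceable contract — any decomposition whose product
reconstructs the input and whose sources are uncorrelated will do — and
the implementation matches scikit-learn's FastICA separation quality on
identical data. Gaussian $1/f$ background directions never formally
converge in any FastICA, so the iteration cap (200) is the practical
stopping rule.

## ERP validation workflow

The `erp` module implements the validation used to show that cleaning
removes artifact but keeps signal: epochs of −1.0…0.8 s around gaze-shift
events, baseline −1.0…−0.7 s, ROI averages (frontal pole: Fp1/Fp2/AF3/AF4;
central: C3/Cz/C4; occipital: O1/Oz/O2 — defaults, fully configurable),
and the *adaptive mean* amplitude: find the sample of maximum absolute
amplitude within ±50 ms of the window centre (earliest sample on ties),
then average ±10 ms around that peak. Peak polarity is deliberately
unsigned because infant components are often negative-going. The frontal
pole is measured at −100…100 ms (saccade artifact), occipital and central
at 200–300 ms (visual response).

## The synthetic generator

Because real infant recordings cannot be shipped, every test runs on
seeded synthetic data (`synthetic_spec()` defaults: 32-channel 10–20
montage, 512 Hz, 120 s):

* **neural_alpha** — $1/f^\lambda$ noise ($\lambda \sim U(0.8, 1.6)$) plus
  a narrowband oscillation at $U(6,9)$ Hz (infant mode; $U(9,13)$ adult),
  projected through a random dipole of the same three-shell head model.
* **neural_broadband** — pure $1/f^\lambda$ with a dipolar map.
* **blink** — sparse positive 0.2–0.4 s pulses every 1.5–4 s on a frontal
  Gaussian map (jittered centre and width, so no two maps are collinear).
* **lateral_eye** — step transients with 50 ms edges, left–right
  antisymmetric frontal map.
* **muscle** — noise with power rising above ~15 Hz on a temporal-rim map.
* **channel_pop** — near-delta map on one electrode with a heavy-tailed,
  jumpy source.

Labels are +1 for the last four classes. `make_labelled_corpus()` blends
each component with a random fraction ($0.7 \times \mathrm{Beta}(1,2)$,
i.e. usually mild, occasionally substantial) of independent $1/f$
background and perturbs its map proportionally. This mirrors the essential
property of real training corpora: they are built from ICA *estimates*,
which always carry some admixture of other sources. Without it, a
classifier trained on implausibly pure components fails on actual ICA
output — exactly the regime the tests exercise.

`make_recording()` projects about ten background components (at most one
blink and one lateral-eye source — a recording has one pair of eyes) plus
spatially smoothed pink sensor noise with an iid white floor (SNR 3 by
default). An optional ERP scene adds a saccade-locked frontal transient
(15 µV RMS, per-event size $U(0.4, 2)$, plus non-event-locked ocular
transients about every 4 s) and a fixation-locked occipital response
(Gaussian peaking at +250 ms, 1.5 µV RMS against an ongoing 6–9 Hz
rhythm; single-trial response SNR below one, as in real ERP data, so the
response is only visible after averaging).

What the generator does *not* emulate: real head geometry (idealised
spherical model, no BEM), heartbeat artifact, cap-pull fussing beyond
gross bursts, non-stationary source amplitudes, or volume-conduction
consistent noise. Passing tests therefore demonstrate that the algorithms
implement their contracts and that the pipeline separates *this* family of
sources; they do not certify classification accuracy on real infant data,
where reported agreement with expert labels is in the 70–80 % range, not
the >90 % seen here.

## Numerical and design choices

* **Problem sizes.** The standard study conditions used throughout tests
  and the acceptance script: 600 training + 600 held-out components,
  120-s sources at 512 Hz, 40-event ERP scenes, a 200-iteration ICA cap.
  A full acceptance run takes a few minutes on one CPU.
* **Sign/scale convention.** Mixing columns are normalised to unit norm
  with their largest-magnitude entry positive; sources absorb the scale.
  Needed to make features well defined; applied on construction.
* **Label encoding.** Artifact = +1 so that "reject" is the positive
  class of the decision function.
* **Tie-break.** $w\cdot z + b = 0$ classifies as neural (retain when in
  doubt).
* **Degenerate inputs.** Constant patterns, constant feature columns,
  single-class training sets, too-short signals and over-wide bands all
  raise typed errors (`icaclean_*_error`) rather than propagating NaN; a
  component whose features cannot be computed yields a flagged NA row,
  not a crash.
* **Filter edge handling.** Reflection padding before FFT convolution;
  the first/last `taps` samples are still best treated as burn-in, which
  is why the idempotence property is assessed away from the edges.
* **Idempotence and transition bands.** The published 25 %-transition
  designs attenuate transition-band content (0.75–1 Hz, 20–25 Hz) a
  little further on *every* pass, so repeated preprocessing of broadband
  $1/f$ data keeps changing a few percent of RMS indefinitely; inside the
  passband a second run changes the signal by well under 1 %. The
  idempotence test states the property on passband-limited data
  accordingly.
* **Interpolation accuracy.** A degree-2 spherical-harmonic field is
  rebuilt at a dropped mid-scalp electrode to within 5 % relative RMS;
  rim electrodes (Fp/O row) are partially extrapolated and can reach
  ~8 % — a known limitation of spline interpolation at the cap boundary.
* **EDF output.** 16-bit with a symmetric per-channel physical range
  (text-exact to 6 significant digits), so a write/read round trip is
  exact to one quantisation step.

## Limitations

The classifier is linear: classes that are not linearly separable in the
six features (heavily mixed components above ~50 % admixture) are
genuinely ambiguous, which matches the inter-rater disagreement seen among
human experts. The current-density feature degrades on low-density
montages; it is retained because it still separates focal from dipolar
maps at 32 channels, but its weight should be expected to shrink when
training on sparser caps. Training data low-passed at 20 Hz cannot teach
the classifier anything about artifact above 20 Hz; use the 40 Hz
configuration with a matching training set if higher-frequency content
matters.
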