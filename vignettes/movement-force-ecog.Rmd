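---
title: "Decoding movement and force from motor-cortical ECoG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement and force from motor-cortical ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecogrip` analyzes sequential movement–force motor tasks recorded with
high-density electrocorticography (ECoG): a subject is cued, executes a
self-paced finger flexion, contacts a force sensor, and presses to a randomly
varying force target. The package asks whether the *premovement*, *movement*,
and *force* behavioral modes have distinct cortical representations, using
five complementary analyses: continuous decoding, spatial decoding maps,
latent-dynamics denoising, a neural vector angle, and discrete mode
classification. Because such recordings are rarely shareable, the package
ships a synthetic session generator with known ground truth; every analysis
stage is validated against what was planted.

# Spectral features

Each electrode is reduced to two band-power features per 25-ms time bin:
broadband low frequency (8–55 Hz, typically suppressed during movement) and
broadband high frequency (70–150 Hz, typically elevated with local cortical
activation). The estimator follows the event-related spectral perturbation
convention: a 256-ms Hanning window hops in 25-ms steps (231 ms overlap); at
2 kHz this gives a 512-sample FFT and a frequency resolution of
2000/512 = 3.90625 Hz. Log power per frequency bin is normalized by
subtracting, per channel and frequency bin, the log of the mean power over
the entire record; the feature is the mean of the normalized values over the
bins whose centers fall inside the band (edges inclusive).

Numerical choices worth knowing:

* **Log base and guard.** Natural log, with `1e-12` added before taking logs
  so silent synthetic channels do not produce `-Inf`.
* **Normalization offset.** Normalizing the log power by the log of the
  *mean* power leaves a constant offset: for stationary noise the per-bin
  power is approximately exponential, so the normalized log has expectation
  `digamma(1) = -0.5772`, not 0. The features are used in models with
  intercepts, so the offset is irrelevant downstream, but tests assert it
  explicitly rather than pretending the mean is zero.
* **Bin timestamps** are window centers; all intervals are half-open
  `[start, end)`; bins are assigned to trial windows by their center time.
* **Lagged design.** The decoding design matrix concatenates each bin with
  its nine causal predecessors (10 lags), giving
  `M = 2 × electrodes × 10` columns; rows with incomplete history are
  dropped.

# Behavioral events

The movement signal is the first principal component of the index-finger
glove sensors over the session, sign-oriented so flexion is positive (the
excursion away from the resting median is taken as the flexion direction).
Movement onset is the first post-cue time the signal exceeds its pre-cue
baseline mean + 3 SD (300-ms baseline) for at least 50 ms sustained; force
onset is the first crossing of 2% of the session's maximum force; peak force
is the within-trial argmax. The downstream analyses never depend on the
specific detector, and all three thresholds are arguments. Mode labels are
`premovement` from cue to movement onset, `movement` to force onset, and
`force` for the first 0.5 s of force (truncated to keep class sizes
comparable); everything else is unlabeled and excluded from classification.

# Continuous decoding (Wiener cascade)

Movement and force are decoded independently from the same lagged feature
matrix by a Wiener cascade: a ridge-regularized linear filter followed by a
static third-order polynomial fit to the training-set linear output.
Accuracy is the fractional variance accounted for,
`FVAF = 1 − SSE/SST`, uncapped below; 1 is perfect, 0 is the mean predictor.
Cross-validation uses 11 contiguous time blocks — 9 for training, 1 for
selecting the ridge penalty, 1 for testing — because the lagged features
overlap in time and shuffled folds would leak.

The ridge penalty is selected per fold from a log-spaced grid of 13 values,
`1e-4` to `1e8`, by validation-fold FVAF with ties going to the smallest
penalty. The upper end of the grid matters: an uninformative target (e.g., a
circularly shifted trace) is only scored near zero if the grid contains a
penalty large enough to collapse the filter to an effectively constant
prediction; with a grid capped at `1e4` every candidate still overfits
hundreds of correlated columns and the test-fold FVAF is biased negative
(about −0.15 in our null experiments). When the linear output is nearly
constant the cubic stage degenerates; it is then replaced by the training
mean to avoid wild extrapolation.

# Spatial decoding maps

Each electrode is decoded alone (its 2 bands × 10 lags), and the per-fold
test FVAF over the grid forms a decoding map (10 folds by default). Two
statistics compare movement and force maps:

* **Peak displacement** — Euclidean distance (mm) between argmax electrodes,
  computed per fold between the movement and force maps of the same fold;
  ties broken row-major.
* **Map distance `D`** — the maps are treated as images with FVAF pixel
  intensities clipped to `[0, 1]`; `D` is the Euclidean distance between two
  maps divided by `sqrt(n_electrodes)` (the maximum possible distance), so
  `D ∈ [0, 1]`. Negative FVAF is clipped only for map construction.

`D_inter` (movement fold *i* vs force fold *j*) is compared with `D_intra`
(within-mode fold pairs, the control that varies only with time) by a
one-tailed Wilcoxon signed-rank test. The fold pairs entering the test are
*disjoint* by default — each fold appears in exactly one pair, with the
cross-mode distance of the pair matched against the mean of the two
within-mode distances for the same folds. Using every fold pair gives more
pairs but they share folds, and the signed-rank test then rejects too often
under exchangeable inputs (we measured ≈6.5% at nominal 5% on independent
random maps, and worse on sessions); the all-pairs variant remains available
via `test_pairing = "all"`, and the reported distance summaries always use
all pairs. A Bonferroni factor for multi-session batches is an argument.

One subtlety the synthetic experiments expose: even when the two gain-map
peaks coincide, movement and force maps are *not* exchangeable — the two
behavioral targets differ in their time courses, so electrodes decode them
with different accuracy, and `D_inter > D_intra` is a true positive. Type-I
calibration of the test is therefore checked by splitting same-mode maps
into two pseudo-mode groups, which is exchangeable by construction.

# Latent dynamics: Gaussian-emission sequential autoencoder

Continuous z-scored features call for Gaussian rather than Poisson
emissions. The model is a variational sequential autoencoder with autonomous
dynamics:

* a bidirectional recurrent encoder maps each trial's window to a Gaussian
  posterior over the generator's initial condition;
* an autonomous recurrent generator (tanh units) unrolls from a sampled
  initial condition;
* latent factors `f_t` are a time-invariant linear readout `W_fac` of the
  generator state;
* each feature `x_t` is modeled as `N(mu_t, sigma_t^2)` with
  `mu_t = W1 f_t + b1` and `sigma_t = 1e-3 + softplus(W2 f_t + b2)`, both
  readouts fixed across time. The softplus-plus-floor keeps `sigma > 0`
  (a raw linear map can go non-positive and destroy the likelihood).

Training maximizes the evidence lower bound (Gaussian log likelihood minus
the KL of the initial-condition posterior from a standard normal prior) with
full-batch Adam, a linear KL warm-up over the first 20% of epochs, and a
0.993 per-epoch learning-rate decay. Implementation is plain R with
hand-derived backpropagation through time; the gradients are verified
against central finite differences in the test suite (worst relative error
below `1e-4` at the tested points). Loss spikes of a few percent of the
total decrease can still occur mid-training — convergence is therefore
monitored on a sampling-free curve (the posterior-mean ELBO at full KL
weight, recorded each epoch) rather than the stochastic training loss, and
divergence (non-finite loss) aborts with the epoch and seed.

Defaults: encoder size 32, generator size 48, factors = half the feature
count capped at 16, 300 epochs, inferred-input/controller pathways omitted
(initial-condition-only dynamics). Separate models are fit per band; windows
are −1.5 s to +0.75 s around force onset, which covers premovement through
the truncated force mode. Denoising runs the model at the posterior mean.
The denoised features are summarized by the number of principal components
needed for 90% of the variance; a rank-`K` bottleneck necessarily compresses
this relative to the raw features, and the factor-recovery benchmark (3
planted latent factors, 40 features, 60 trials, observation noise SD 0.5)
reaches a mean canonical correlation above 0.98 in about 30 s on one CPU.

The benchmark generates data from an autonomous linear dynamical system
because the model itself assumes trial-to-trial variability enters only
through the initial condition; data driven by mid-trial inputs would need
the controller variant, which is out of scope.

# Neural vector angle (NVA)

To summarize population state in units that pool across sessions, features
are first screened by k-means (k = 3, 20 restarts, squared-Euclidean
distance on trial-averaged z-scored peri-event traces, silhouette values
reported). Of the three clusters the two with the largest modulation depth
(peak-to-trough of the cluster centroid) are selected and tagged low/high by
the majority band of their members; the remainder is typically the poorly
modulated cluster. An explicit depth criterion is needed for automation even
though on well-structured sessions the same two clusters emerge on their
own.

For each selected cluster the neural vector `m(t)` collects the member
features; it is smoothed with a *centered* 5-bin moving average (125 ms;
centered avoids biasing onset-timing claims), and the angle
`theta(t) = acos( m(t)·m_ref / (||m(t)|| ||m_ref||) )` in degrees is taken
against the per-trial reference `m_ref`, the mean of `m(t)` over the 250 ms
before peak force. Angles are scale-invariant and bounded in `[0°, 180°]`;
bins whose vector norm falls below `1e-9` are reported missing. Mode
differences are tested by Kruskal–Wallis across premovement/movement/force
angle samples with Tukey HSD on ranks as the post hoc.

# Mode classification

Every labeled 25-ms bin is classified as one of the three modes from the
same lagged features used for continuous decoding, with 5-fold contiguous
cross-validation. Classifiers: radial-basis SVM (one-vs-one) and bagged
trees (100 trees, all features available at each split — bagging without
feature subsampling). Chance level is the accuracy distribution under label
permutation; labels are permuted in whole-trial blocks by default because
bins are strongly autocorrelated and per-bin shuffling understates chance.
The desk default is 200 shuffles (1000 reproduces the full procedure), and a
majority-class predictor is available for fast chance estimation — with
unbalanced classes chance concentrates near the largest prior, not 1/3. The
balanced-class sanity check (mean chance 1/3) holds at session scale; at a
few hundred bins the finite label population induces a small negative
train/test anticorrelation bias that the tests document rather than hide.

# The synthetic session generator

The generator emulates the task at the signal level so every downstream
stage has a known answer:

* **Timing.** Per trial: premovement duration from a truncated normal
  (mean 0.8 s, SD 0.15 s, floor 0.1 s), movement likewise (mean 0.4 s), a
  fixed 1.0-s force hold, and a 1.0-s inter-trial delay; with jitter off the
  cue-to-cue gap is exact. Force targets are uniform on [0.2, 1] of maximum
  force. These choices reproduce ~2.5-s trials.
* **Carriers.** Each electrode sums two band-limited Gaussian-noise carriers
  (8–55 and 70–150 Hz, brick-wall FFT masks), not sinusoids: Hanning/FFT
  band power of a pure sinusoid is degenerate, whereas modulated noise
  behaves like real field potentials.
* **Modulation.** The log amplitude of each carrier is driven by smooth
  envelopes locked to movement and/or force onset — high band up, low band
  down — weighted by two smooth unimodal Gaussian gain maps whose argmax
  electrodes are planted exactly `planted_peak_shift_mm` apart. Each
  electrode is movement-locked, force-locked, or both with probabilities
  (0.3, 0.3, 0.4), reproducing the heterogeneous locking seen in real
  sessions; the two peak electrodes are always locked to both so the planted
  peaks survive. Shared low-dimensional latent traces (smoothed Gaussian
  noise on a 25-ms grid) load onto channels with gains gated by the planted
  maps, so unmodulated sites stay exactly silent in the planted log
  amplitude.
* **Behavior.** Glove sensors are scaled copies of the flexion envelope plus
  sensor noise; the force trace ramps to the trial target with a small
  overshoot 0.35 s after onset (making peak-force time well defined).
* **Noise.** White noise with SD = carrier RMS / `snr`; `snr = Inf` removes
  it. Even then, windowed band power of a stochastic carrier keeps
  irreducible chi-square estimation noise; exact zero-variance claims hold
  at the level of the planted log amplitude (which is exactly rank
  `latent_dim + 2`: two event envelopes plus the latents), and the tests
  check the feature-level versions up to that estimation noise.

What the generator does *not* emulate: biophysical cortical sources, volume
conduction, 1/f background spectra, movement artifacts, electrode noise
heterogeneity, or behavioral errors beyond timeout trials. Passing tests
therefore demonstrate that the analysis code recovers what it is supposed to
recover from data with the assumed structure — not that real cortical data
have that structure.

# Problem sizes and reproducibility

The documented desk scales are: 4×4 grids with 10–60 trials for decoding and
map experiments (a full 8×8, 60-trial session is the generator default and
runs in a few minutes), 60-trial/40-feature benchmarks for the latent model,
and 200-shuffle chance distributions. Every stochastic step takes an integer
seed, and the whole pipeline (`run_pipeline()`) is bit-reproducible under a
fixed seed; session containers are written as a versioned RDS schema with a
provenance block (seed, config hash, package version) and CSV/JSON sidecars
for the tabular outputs.

# Known limitations

* The signed-rank comparison of decoding maps is only calibrated with the
  disjoint pairing; the all-pairs variant is kept for comparability but is
  anticonservative.
* The latent model is the autonomous variant; sessions whose single-trial
  variability is driven by unpredictable mid-trial inputs are outside its
  model class.
* The onset detector is threshold-based and tuned for clean synthetic
  traces; noisy human kinematics may need different thresholds (all
  exposed).
* Band boundaries are fixed constants (8–55, 70–150 Hz); the data-driven
  band discovery that originally motivated them is dataset-specific and not
  re-run here.
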