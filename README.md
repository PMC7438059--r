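# ecogrip

Analysis of sequential movement–force motor tasks recorded with high-density
electrocorticography (ECoG). The scientific question: when a person flexes a
finger and then presses it isometrically against a sensor, do the
*premovement*, *movement*, and *force* phases of the behavior have distinct
representations in motor and premotor cortex? `ecogrip` implements the full
analysis chain for that question and a ground-truth synthetic session
generator, so every stage can be validated without access to clinical
recordings.

## What the package computes

**Spectral features.** Per electrode and 25-ms bin, mean normalized log power
in two bands — broadband low frequency (8–55 Hz) and broadband high frequency
(70–150 Hz) — from 256-ms Hanning-windowed FFTs (frequency resolution
fs/512 = 3.9 Hz at 2 kHz), normalized by the log of the mean power over the
record. Decoders consume the lagged design matrix with 10 causal bins of
history (`M = 2 × electrodes × 10` columns).

**Continuous decoding.** A Wiener cascade — ridge-regularized linear filter
plus a static third-order polynomial,

> ŷ(t) = P₃( Σ_{m} w_m X_{t,m} + b ),

scored by the fractional variance accounted for,
FVAF = 1 − Σ(y−ŷ)²/Σ(y−ȳ)², under 11-fold contiguous-block cross-validation
(9 train / 1 ridge-validation / 1 test folds).

**Spatial decoding maps.** Per-electrode single-channel decoders give one
FVAF map per cross-validation fold and mode. Representation differences are
quantified by the displacement of the map peak (mm) and by the normalized
map distance D = ‖map₁ − map₂‖₂ / √n ∈ [0, 1], with between-mode D_inter
tested against within-mode D_intra (one-tailed Wilcoxon signed-rank over
disjoint fold pairs).

**Latent dynamics.** A Gaussian-emission sequential autoencoder (a
variational recurrent autoencoder with autonomous dynamics): factors
f_t are a fixed linear readout of the generator state, and each z-scored
feature is modeled as x_t ~ N(W₁f_t + b₁, (softplus(W₂f_t + b₂) + 10⁻³)²).
Implemented in base R with hand-derived, finite-difference-verified
backpropagation through time. `denoise()` returns factors, denoised
features, and their principal components; `pcs_for_variance()` reports the
component count needed for 90% variance.

**Neural vector angle (NVA).** After k-means selection of the well-modulated
low- and high-frequency feature clusters, θ(t) = acos(m(t)·m_ref /
‖m(t)‖‖m_ref‖) in degrees, where m(t) is the 5-bin-smoothed cluster vector
and m_ref its mean over the 250 ms before peak force. Kruskal–Wallis with
Tukey-on-ranks post hocs tests mode differences.

**Mode classification.** Per-bin 3-class SVM or bagged-tree classification
with 5-fold contiguous cross-validation and a trial-block label-permutation
chance distribution.

**Synthetic sessions.** `simulate_session(sim_config(...))` builds a
session: amplitude-modulated band-limited noise carriers with planted gain
maps (known peak shift), heterogeneous movement/force locking, shared latent
traces, glove-like kinematics, a force trace with random targets, and
per-sample ground-truth labels.

## Worked example

```r
library(ecogrip)

cfg <- sim_config(n_trials = 24, n_rows = 4, n_cols = 4, snr = 8, seed = 33)
ses <- simulate_session(cfg)
ses$recording
#> <ecog_recording> 16 channels x 154052 samples @ 2000 Hz (77 s), 24 cues

fe <- compute_band_features(ses$recording)
fe
#> <feature_tensor> 3071 bins x 32 features (256-ms window, 25-ms step, 3.906-Hz resolution)

des  <- build_lagged_design(fe, 10)
mv   <- kinematic_pc1(ses$recording$kinematics)
y_mv <- align_target(mv, ses$recording$fs_hz, des$bin_times)
y_fr <- align_target(ses$recording$force, ses$recording$fs_hz, des$bin_times)

crossval_decode(des, y_mv)
#> <cv_result> 11 folds; test FVAF median 0.962 (IQR 0.0244)
crossval_decode(des, y_fr)
#> <cv_result> 11 folds; test FVAF median 0.848 (IQR 0.164)

maps_mvt <- single_electrode_maps(fe, y_mv, "movement")
maps_frc <- single_electrode_maps(fe, y_fr, "force")
compare_inter_intra(maps_mvt, maps_frc)
#> <map_comparison> median D_inter 0.238 vs D_intra 0.153; displacement 8.6 +/- 2.92 mm; p = 0.0312 (one-tailed signed-rank)
```

Reading the numbers: both behaviors decode well from the full grid (median
test FVAF 0.96 for kinematics, 0.85 for force). The per-electrode maps of
the two modes differ more between modes than within a mode (D_inter 0.24 vs
D_intra 0.15, one-tailed signed-rank p = 0.031), and the recovered peak
displacement, 8.6 ± 2.9 mm, matches the 8-mm separation planted between the
movement and force gain maps in this synthetic session.

`run_pipeline(cfg, out_dir = "out")` executes the whole chain — simulation,
features, event detection, decoding, maps, latent-dynamics denoising, NVA,
and classification — and writes `trials.csv`, `maps.csv`, `nva.csv`, and a
JSON report with per-stage summaries and timings. The methods vignette
(`vignettes/movement-force-ecog.Rmd`) documents the model assumptions,
parameter defaults, and numerical choices.

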