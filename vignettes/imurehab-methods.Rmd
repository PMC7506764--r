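---
title: "Models and design choices in imurehab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in imurehab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A wrist-worn inertial sensor streams three accelerometer channels (in g,
calibrated to ±16 g) and three gyroscope channels (in deg/s, ±2000 dps).
During a local-muscular-endurance (LME) exercise the limb moves
periodically, with one repetition taking roughly 4 s, and each exercise
expresses most of its motion on one *dominant* sensor channel — e.g. bicep
curls on accelerometer X, trunk twists on gyroscope Y. The package
implements and compares three pipelines over this signal model: windowed
time/frequency features into classical classifiers; peak detection on the
smoothed dominant axis; and rasterized signal images into a convolutional
network, including a binary Peak/NoPeak formulation whose label sequence is
transition-halved into a repetition count.

# The synthetic trial generator

No public recordings ship with the package, so every pipeline is exercised
against a seeded generator (`simulate_exercise()`, `simulate_others()`,
`make_dataset()`) whose defaults define the study conditions used by the
test suite and the acceptance script.

**Waveform.** One repetition is one period of
$$s(\phi) = \sin(2\pi\phi) + \sum_{k\ge 2} h_k\,
  \bigl[\sin(2\pi k \phi + \psi_k) - \sin(\psi_k)\bigr],$$
scaled by the profile amplitude. Harmonic amplitudes are kept at
$h_k \le 0.22$ so the derivative has exactly two zeros per period — one
maximum, one minimum — which is what makes ground truth well defined. The
phase offsets $\psi_k$ (default $-\pi/2$) matter: a sum of *pure* sine
harmonics is antisymmetric about the half period, so its positive and
negative excursions are exactly equal and a "global extremum" would be
ambiguous. The offsets break that symmetry and place the larger excursion
early in the cycle, emulating a fast concentric / slower eccentric
movement; the constant correction keeps $s$ exactly zero at repetition
boundaries so per-repetition amplitude jitter introduces no jumps.

**Channels.** The dominant channel carries the waveform at the profile
amplitude (0.35–1.1 g or 120–200 dps across the ten defaults). The five
secondary channels receive phase-shifted fundamentals at cross-coupling
fractions below 0.6 of the *range-scaled* dominant amplitude, which
guarantees mean-square dominance of the configured channel. Accelerometer
channels add a constant gravity projection (per-profile wrist orientation,
norm ≈ 1 g). Gaussian noise is added per channel at `noise_sd` (default
0.05) times the range-scaled dominant amplitude.

**Modes.** Constrained trials (video-paced) use fixed period and amplitude.
Unconstrained trials draw per-repetition period jitter (±10%) and amplitude
jitter (±15%) from the seeded stream and apply a small fixed 3D rotation
(2–10°) to both sensor triads, emulating a different plane of limb movement
and rest position. The jitter defaults are package choices — the
variability of memory-paced exercise is not quantified anywhere we could
copy it from — and are configurable per profile.

**Others.** The non-exercise class is a train of half-cosine transients
with random channels, amplitudes, durations (0.4–2 s) and gaps (0.3–2.5 s);
the random gaps destroy sustained periodicity, which the tests verify via
the autocorrelation at the 4 s exercise lag.

**What the generator does not model:** soft-tissue artifacts, sensor drift
and bias instability, heteroscedastic noise, fatigue-induced slowing within
a set, and genuinely ambiguous movements between classes. Passing tests on
this generator therefore demonstrate the *correctness of the pipelines*
(segmentation arithmetic, feature definitions, counter logic, training
mechanics) and the *internal consistency* of the methods, not field
accuracy on real wrist recordings.

# Segmentation and features

Windows are `W = round(length_s * fs)` samples with stride
`S = round(stride_s * fs)`; the count is `floor((N - W)/S) + 1`. Feature
windows default to 50% overlap. The image pipeline uses a 0.5 s stride:
of the two windowing conventions in circulation for this task (a "1 s
overlap" and "43 windows per 25 s"), only a 0.5 s stride reproduces the
43-window arithmetic, so 43 is taken as normative and the stride is left
configurable.

The 48 features are, per channel: min, max, mean, sample standard
deviation, RMS, histogram entropy, spectral energy; plus six within-sensor
Pearson correlations — the only pairing consistent with a total of 48.
Two estimators needed definitions the task description leaves open, so the
package fixes testable ones:

* **Entropy**: Shannon entropy of a 16-bin equal-width amplitude histogram
  spanning `[min, max]`, in bits; a constant series occupies one bin
  (entropy 0) and a uniform occupancy gives `log2(16) = 4`.
* **Energy**: `sum(|X_k|^2)/W^2` over the DFT of the mean-removed window,
  DC excluded — i.e. the population time-domain variance, by Parseval.
  This makes the feature offset-invariant and gives the unit-sine value
  0.5 in closed form. (A `1/W` normalization would instead scale with
  window length, which breaks comparability across the 1 s / 2 s / 4 s
  window settings.)

Zero-variance correlation pairs are defined as 0. PCA standardizes by
training mean and standard deviation (zero-variance columns get scale 1
with a warning), and retains the smallest leading set of components whose
accumulated variance fraction exceeds the threshold (default 0.99); if no
prefix exceeds it — threshold 1.0 — the full rank is retained.

# The classifier harness

Grid search is exhaustive over the spec'd grids with stratified k-fold
(default 10) cross-validation; fold assignment deals a seeded within-class
shuffle round-robin so every fold contains every class. The selection
metric is mean held-out accuracy, ties broken by grid order. The SVM is
one-vs-rest over binary RBF/linear machines (the underlying library's
native multiclass scheme is one-vs-one, so the OvR margins are assembled
explicitly and their orientation is checked on the training data). The MLP
is a single-hidden-layer network whose regularization step α is the
gridded hyperparameter on a log scale from 1e-5 to 1e3. Default grids
contain the reference optima (RBF, C = 100, γ = 0.01; k = 1; 10 trees;
α = 1).

"Overall" precision/recall/F1 are **macro** averages: the synthetic (and
intended real) datasets are near-balanced, and macro is the convention that
exposes per-class failure. Precision of a never-predicted class is defined
as 0 with a warning rather than NaN, so reports are always numeric and the
policy is visible. Model comparison ranks by validation accuracy with the
documented tie order svm > mlp > knn > rf.

# Peak-detection counting

The dominant channel maximizes the mean square of the mean-removed,
range-scaled channels. Two choices here are deliberate:

* **Mean removal** — otherwise the accelerometer's gravity offset dominates
  the mean square and would mask the actual motion axis.
* **Range scaling** (divide by 16 g / 2000 dps) — the comparison crosses
  sensors with incommensurable units; scaling by the calibration range
  makes a 1 g arm swing and a 125 dps wrist rotation comparable rather
  than letting raw deg/s numbers always win.

Smoothing is Savitzky–Golay, order 4, window ≈ 2 s forced odd (1023
samples at 512 Hz; at other rates the window rescales to keep the same
temporal support). Cut-offs are `median ± k (q95 − q5)/2` with k = 0.3:
the quantile-based amplitude is robust to outliers, translation- and
scale-equivariant (so the counter is invariant to offset and positive
scaling), and makes the degenerate flat-signal case explicit. The detector
is a two-state machine: a candidate maximum must exceed the upper cut-off
and is confirmed when the signal falls back below it, then symmetrically
for minima — the cut-off pair acts as a hysteresis band, so cycles whose
excursion stays inside the band are skipped, and a monotone signal yields
nothing. Each completed max–min pair is one repetition. Per-exercise
configurations can be tabled by class label; the ten defaults differ only
by dominant axis, matching the one-detector-per-exercise design.

# Signal images and the binary labelling

Rasterization is a pure function of (window, config): all six traces are
overlaid on one square canvas (background 0, trace 1, no anti-aliasing, no
plotting device), columns map time and rows map amplitude within fixed
per-sensor limits. Fixed limits — not per-window autoscaling — preserve
amplitude information across windows; the defaults are the calibration
ranges (±16 g, ±2000 dps). For desk-scale training on the synthetic
regime (~1 g / ~200 dps signals) the tests and the acceptance script
configure ±2 g / ±250 dps so the traces keep useful vertical resolution
after downsampling to 64 px; with full-range limits a 1 g trace occupies
about two pixel rows at that size. Downsampling from the 576-px canvas is
exact area averaging (a precomputed linear operator on rows and columns),
chosen over low-resolution plotting because it is deterministic across
platforms.

A window's binary label is 1 ("Peak") when the global extremum — the
sample with the largest absolute deviation from the segment median, after
Savitzky–Golay smoothing — of the dominant-axis segment lies strictly in
the left half of the window, 0 otherwise; an extremum exactly at the
midpoint is NoPeak, and a constant segment is NoPeak with a degenerate
flag.

# The CNN

The topology is fixed at 5 convolutional + 3 fully connected layers with
batch normalization after every convolutional and hidden dense layer, ReLU
activations, and dropout 0.4 in the dense layers. At input 227 and width
multiplier 1 the kernels and widths are the canonical values of this
architecture family (11×11 stride 4 stem; 96/256/384/384/256 filters;
4096-unit dense layers). The desk-scale default — input 64, multiplier
0.25, ≤ 20 epochs, batch 32 — trains in minutes on one CPU; incompatible
input sizes fail at build time naming the first failing layer.

The engine itself (im2col convolution over BLAS GEMM, max pooling, batch
normalization, dropout, SGD/Adam/RMSprop, cross-entropy /
Kullback–Leibler / binary cross-entropy losses) is implemented in the
package and verified by finite-difference gradient checks in the test
suite. With one-hot targets the KL divergence equals the cross-entropy
(the target entropy term is zero), so the two multiclass losses share a
gradient path. All shuffling, initialization and dropout derive from one
seed; two runs with identical data and config are bitwise-reproducible,
and the checkpoint kept is the epoch with minimum validation loss.
Resizing and shuffling are the only augmentations: shear, flips and
rotations are excluded because the images encode time series, whose
orientation is meaningful.

Desk-scale training runs use Adam at learning rate 1e-3 — the upper end of
the swept range [1e-6, 1e-3], appropriate for a 0.25-width network on a
few hundred images; the binary-head default of 1e-5 mirrors the optimum
reported for full-scale training and is kept as the configuration
default.

**Transition counting.** The repetition count of a binary label sequence
is the number of maximal runs of 1. On sequences that start and end at 0
this equals transitions/2 exactly (the test suite checks 10,000 random
cases against that oracle); "half the transitions" alone is ill-defined
when a sequence starts or ends mid-Peak, and the run rule deterministically
counts such boundary repetitions as one.

# Numerical and degenerate-input policy

* Validation errors name the violated invariant (label set, monotone time,
  sensor ranges, channel lengths).
* A recording shorter than one window yields an empty window list (and a
  0 count) with a warning, not an error.
* Savitzky–Golay windows longer than the signal shrink to the largest
  valid odd length with a warning.
* Flat signals propagate an explicit degenerate flag through thresholds
  and counting (count 0), never NaN.
* Ties: dominant-axis ties resolve in channel order acc X/Y/Z, gyro X/Y/Z;
  grid-search ties resolve in grid order; comparison-table ties in the
  algorithm order svm > mlp > knn > rf; a window extremum exactly at the
  midpoint labels NoPeak.

# Problem sizes in the shipped tests and acceptance run

The suite and `scripts/acceptance.R` use 64 Hz trials of 5–8 repetitions
(the 4 s period regime), a 4-subject dataset tree (2 train / 1 validation
/ 1 test subjects × 11 classes), 10 × 20 seeded noisy trials for counting
accuracy, 10 × 100 seeded trials for dominant-axis identification, and a
binary CNN trained for 8 epochs on ~400 64-px images from five classes
with ~200 validation images. These sizes were chosen as the smallest at
which every property under test is comfortably away from its sampling
noise; all of them are parameters, and the full-scale settings (512 Hz,
227-px images, multiplier 1) remain available behind the same interfaces.

# Known limitations

* The synthetic generator's separability makes recognition easy; perfect
  desk-scale classification scores say nothing about accuracy on real
  recordings.
* The threshold formula for peak detection is a package convention (the
  method family it belongs to does not pin one down); k = 0.3 is a default,
  not an estimate.
* The CNN engine is single-threaded R + BLAS: adequate for desk-scale
  models, not for 227-px full-width training on large image sets.
* Subject-disjointness checking relies on the `<subject>_<session>_<k>.csv`
  naming convention when scanning foreign trees.
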