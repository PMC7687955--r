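---
title: "Methods: supervised self-organizing maps and spectral unmixing for Raman tissue maps"
author: "skinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised self-organizing maps and spectral unmixing for Raman tissue maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinet)
```

## The problem

Raman microspectroscopy of neural tissue produces hyperspectral maps: a
grid of spectra (here 20 x 20 points at 1.5 um spacing, 400 spectra per
sample) over a 605-1715 cm^-1 fingerprint axis. After traumatic brain
injury (TBI), tissue chemistry shifts subtly — most prominently a
suppression of the CH-bending band near 1266 cm^-1 and the C=C stretch
near 1660 cm^-1, with relative increases near 850, 1098 and 1337 cm^-1.
The analytical task is threefold:

1. classify injury severity (sham / moderate / severe) from individual
   noisy spectra,
2. identify *which* wavenumbers drive that separation, and
3. attribute the changes to tissue components by unmixing average
   spectra against a component library.

`skinet` implements the full chain — synthetic data generation,
preprocessing, a supervised self-organizing map (SOM) classifier with
SOMDI feature extraction, non-negative least-squares (NNLS) unmixing,
and band-ratio imaging — as testable, seeded R code.

## The synthetic-data generator

No measured spectra are distributed with the package, so the generator
is a first-class module: it emulates the statistical structure the
analysis assumes, and every downstream stage is tested against data it
produces with known ground truth.

A clean tissue spectrum is a sum of Gaussian bands (Lorentzian for the
sharp 1003 cm^-1 phenylalanine ring-breathing mode) at 850, 1003, 1098,
1266, 1337, 1447 and 1660 cm^-1, with amplitudes chosen to resemble a
typical fingerprint-region tissue spectrum (CH2 bending at 1447 cm^-1
strongest). Group effects are multiplicative on band amplitudes:

* **sTBI**: x1.15 at 850/1098/1337, x0.85 at 1003/1266/1660;
* **mTBI**: the same directions at x1.07 / x0.93;
* **sham**: all bands at exactly 1.

Animal-to-animal heterogeneity is a per-mouse lognormal multiplier per
band (mean 1), with coefficient of variation 0.10 for mTBI versus 0.05
for sham and sTBI. This ordering is deliberate: it makes severe injury
the most separable group and moderate injury the group most confused
with sham — the qualitative confusion structure the classifier tests
assert. The effect magnitudes themselves are design choices (no effect
sizes are published for this kind of data); they were fixed once,
before any classifier was run, and are exposed as configuration.

On top of the clean signal each spectrum receives

* a random positive cubic baseline (scaled by `baseline_scale`, default
  0.5 for retina presets and 1.0 for brain presets, mimicking stronger
  autofluorescence from haemorrhage at the injury site),
* additive zero-mean Gaussian noise (`noise_sigma`, default 0.05 —
  roughly 5% of the strongest band, i.e. visibly noisy single
  acquisitions), and
* a Poisson-distributed number of single-channel cosmic-ray spikes per
  map (default mean 5) at amplitude 20x the map's 95th intensity
  percentile. The large amplitude makes the removal oracle unambiguous:
  every injected spike is recorded in the map's provenance so tests can
  verify repairs coordinate-by-coordinate.

Additive Gaussian noise was preferred over Poisson shot noise because
no downstream method assumes a noise family; the simpler model keeps
the law-of-large-numbers tests exact. What the generator does **not**
emulate: instrument line-shape functions, detector etaloning, spatial
autocorrelation of chemistry within a map, water/PBS background, and
real biological covariance between bands. Passing tests therefore
demonstrate the *algorithms* behave correctly under the assumed
structure, not that real tissue will classify at any particular
accuracy.

The default design reproduces the study layout exactly: 3 groups x 6
mice x 2 eyes x 400 spectra = 14,400 retina spectra (4800 per group),
and 3 x 6 x 1 x 400 = 7200 for brain.

## Preprocessing

**Cosmic-ray removal.** "Nearest neighbour" removal is interpreted
spatially: for each spectrum, each channel is compared against the
median of its 4-connected grid neighbours at that channel. A channel is
repaired (replaced by the neighbour median) when its positive residual
exceeds `cosmic_k` (default 8) robust standard deviations, where the
robust scale is the MAD of that spectrum's residuals. Cosmic rays are
single-acquisition, single-channel events, so spatial neighbours are
clean references; the threshold of 8 MADs leaves smooth baseline
differences and ordinary noise untouched (the no-spike null is a test).
An alternative reading — neighbours along the wavenumber axis — exists;
the spatial reading was chosen because it needs no assumption about
band widths.

**Baseline subtraction.** Vendor "intelligent spline" fitting is
proprietary; the package implements an iterative lower-envelope natural
cubic spline with the same node count (11). Node windows are spread
evenly across the axis; node values start at window minima; points
below the current spline are lifted onto it so noise dips stop dragging
the envelope down while peaks stay excluded via the window minima; the
fit repeats until node values change by less than 1e-6 (or 50
iterations). The final spline is subtracted from the *original*
spectrum, and the result is deliberately not clipped at zero. The
procedure is positively homogeneous (scaling the input scales the
output), which is asserted as a property test. With 11 nodes over the
1110 cm^-1 axis each window is ~100 cm^-1 wide, comfortably wider than
the ~10-30 cm^-1 band widths, so band peaks survive within 5% — the
recovery tolerance asserted against known cubic backgrounds.

**Normalisation and splitting.** Spectra are scaled to unit Euclidean
norm before SOM training. The original analysis is silent on this; it
is exposed as a flag (`normalize`) and defaults to on because BMU
search uses cosine similarity — classification is scale-free either
way, normalisation only stabilises the weight updates. The train/test
split is stratified: exactly `round(0.2 * n_g)` spectra per group are
reserved, deterministically under `split_seed`.

## The supervised SOM

The SOM is a 20 x 20 hexagonal grid (offset rows shifted by 0.5, row
spacing sqrt(3)/2) of weight vectors with the dimension of a spectrum.
Training presents one spectrum at a time, cycling a seeded shuffle per
epoch; the best matching unit (BMU) is the neuron with the highest
cosine similarity to the input (ties broken by lowest index), and every
neuron updates by

w_i <- w_i + alpha(t) * exp(-d(i, b)^2 / (2 sigma(t)^2)) * (x - w_i)

with d the hex-layout Euclidean distance to the BMU. Defaults follow
the tuned model of the study: 5 epochs (57,600 presentations for an
11,520-spectrum training split), initial learning rate 0.2, initial
neighbourhood sigma = (2/3) x the grid edge.

Choices the source description leaves open, and what was decided:

* **Decay schedules** are unstated; the default is linear decay of
  alpha to 0.01 and sigma to 1.0 over the run — conventional, monotone
  and easy to test. Exponential decay and (for the neighbourhood,
  since the phrase "maintained at 2/3 the edge length" admits a
  constant-radius reading) a constant schedule are available in
  `som_config`; decaying is the default.
* **Initialization** is unstated; neurons start as randomly sampled
  training spectra plus small jitter (sd = 1e-3 x the data scale),
  unit-normalised. Sampling from the data puts neurons on the data
  manifold immediately, which matters under a similarity metric that
  ignores scale.
* **Updates below `alpha * h < 1e-9` are skipped** — at 1e-9 relative
  step the update is far below the accumulated floating-point error of
  the run. Weight norms are tracked incrementally from the convex
  update algebra and refreshed every 512 steps against drift.

Supervision is attached *after* training: `accumulate_hits` counts, per
neuron, how many training spectra of each class chose it as BMU. Labels
never influence weight updates (a label-concatenation variant was
deliberately excluded). Classification reads the class hits at a test
spectrum's BMU and predicts the argmax; a BMU that was never hit falls
back to the nearest hit neuron in hex distance. With 400 neurons and 3
classes some neurons are rarely hit, so the fallback is required; it is
part of the documented contract and the brute-force oracle in the test
suite implements it independently.

**SOMDI.** The discriminant index of class k is computed from
activation shares m[i,k] = hits[i,k] / sum_i hits[i,k]:

SOMDI_k = sum_i (m[i,k] - mean over other classes of m[i,.]) * w_i

— a hit-share contrast weighting of the neuron weight vectors. Positive
entries mark wavenumbers elevated in class k relative to the rest. The
exact normalisation used in the original SOMDI publications is not
reproduced here; this definition keeps the stated semantics (which
spectral features drive the clustering) with a symmetric null that the
tests exploit: identical hit distributions give exactly zero, and
permuted labels give discriminants statistically indistinguishable from
zero at every band centre.

Evaluation repeats training from `repeats = 10` distinct
initializations (seeds `seed + 1 ... seed + repeats`) and averages
row-normalised percentage confusion matrices (rows = actual class, rows
sum to 100), with the per-repeat standard deviation of the diagonal —
the same reporting shape as the study's confusion tables. Stratified
10-fold cross-validation on the training split is provided for model
tuning.

## NNLS unmixing

Per-sample average spectra (maps averaged after cosmic-ray removal and
baseline subtraction) are decomposed over 1200-1714 cm^-1 at 1 cm^-1
increments (515 points, linear interpolation — the same one-dimensional
rescaling the original MATLAB workflow used) against a component
library. The solver is `pracma::lsqnonneg`, the Lawson-Hanson
active-set algorithm behind MATLAB's `lsqnonneg`; tests verify the KKT
conditions (|gradient| < 1e-8 on the active set, gradient >= -1e-8 on
the zero set) on random problems and cross-check constructed mixtures
against an independent projected-gradient solver.

The real fitting library (measured brain-lipid and cytochrome-c
spectra) is not redistributable, so the package ships
`synthetic_component_library()`: synthetic cardiolipin-like (strong
1266 and 1660 cm^-1 bands), cholesterol-like, sphingomyelin-like and
cytochrome-c-like profiles, clearly documented as stand-ins, plus a CSV
loader (`read_component_library`) for real libraries. Because the
injury effect suppresses 1266/1660 and the cardiolipin-like component
carries exactly those bands, fitted cardiolipin coefficients decrease
with injury in the synthetic pipeline by construction — the ANOVA
plumbing is thereby testable end to end, but the synthetic p-values say
nothing about real tissue.

Group comparison is a classic one-way ANOVA (equal-variance
between/within mean-square ratio) plus Welch t-tests of each injury
group against sham, reported raw and Holm-adjusted — the original
analysis names ANOVA and sham comparisons but not a post-hoc procedure,
so both adjusted and unadjusted values are given and neither is
privileged. Degenerate inputs are explicit: zero between-group
variation reports F = 0, p = 1 (with a warning); zero within-group
variance with distinct means reports F = Inf, p = 0.

## Ratio maps and hit maps

The band statistic behind the 1447/1266 cm^-1 ratio images is not
defined in the source description; the default is the window maximum
within +/-8 cm^-1 (robust to +/-2 cm^-1 calibration shifts), with
integrated band area as an option. Pixels with near-zero denominators
(< 1e-9) are flagged invalid rather than dropped, preserving the grid.
Hit maps colour each neuron by the hit-proportion-weighted RGB mix of
class colours (sham black, mTBI purple, sTBI orange by default);
zero-hit neurons are neutral grey.

## Problem sizes used in tests and the acceptance script

Bookkeeping checks run the full default design (14,400 retina / 7200
brain spectra); they are cheap because nothing is trained. The
classification experiments use a reduced design chosen to preserve the
study's structure at lower cost: 3 mice per group, both eyes, 10 x 10
maps (1800 spectra; 1440 train / 360 test), a full 20 x 20 SOM, 5
epochs, 5 independent initializations. At this size the qualitative
confusion structure (sTBI diagonal >= mTBI diagonal; sham-mTBI
confusion exceeding sham-sTBI confusion) is stable across seeds, which
is what the acceptance checks assert — numeric accuracies at this
reduced size are not comparable to a full-design run and are reported
as measurements, not targets.

## Known limitations

* The generator's effect sizes and noise level are plausible but
  invented; absolute classification accuracies on synthetic data carry
  no information about real tissue.
* The lower-envelope spline is a reconstruction of the *intent* of
  proprietary vendor baseline correction, not of its code.
* SOMDI here is one concrete member of the family of hit-share
  contrast definitions; alternatives are pluggable.
* Per-spectrum classification treats spectra as independent although
  spectra from one map share an animal; the per-map design metadata is
  retained so group-aware splits can be built, but the default split is
  per-spectrum, matching the study's counts.
* No proprietary instrument formats are read; users export maps to
  two-column text plus a manifest.
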