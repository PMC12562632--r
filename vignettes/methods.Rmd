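---
title: "Models and methods: hyperspectral prediction of pear quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hyperspectral prediction of pear quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Firmness (FI, in newtons) and soluble solid content (SSC, in percent) are
the two standard indices of pear maturity; their ratio, the
firmness--soluble-solids ratio FSR = FI/SSC, summarizes the texture/sugar
balance of an individual fruit in one number. All three can be estimated
non-destructively from near-infrared reflectance (950--1650 nm), where O--H
and C--H overtone bands respond to water and sugar content, and where the
scattering baseline responds to cell-wall structure (firmness). A
hyperspectral camera provides one such spectrum per pixel, so a fitted
spectral regressor can also be mapped across the fruit surface to render
the spatial distribution of quality.

pearHSI implements the full workflow: reflectance calibration of raw cubes,
elliptical region-of-interest (ROI) extraction, stratified SPXY
partitioning, deep and classical spectral regression, RPD-based evaluation,
maturity-stage classification under leakage-free cross-validation, and
pixel-wise quality maps. Because no fruit data ship with the package, a
synthetic generator emulates the study design the pipeline targets: 600
fruit, five maturity stages (P1--P5) with 120 fruit each, 421 reflectance
bands in 950--1650 nm.

# Calibration and ROI extraction

Raw digital numbers are converted to relative reflectance with white/dark
references, R = (RO − RD)/(RW − RD), elementwise over the cube. Elements
with RW = RD (dead pixels) are set to a configurable fill value (default 0)
and counted in the output metadata rather than raising, so whole-cube
calibration survives isolated dead pixels. Reflectance below 0 is floored
at 0; values above 1 (specular highlights) are retained up to a
configurable ceiling of 1.2.

The ROI is an axis-aligned ellipse, by default with 45/30-pixel semi-axes
(a 90 x 60 pixel ellipse on the fruit's equatorial zone, major axis along
the stem--calyx axis, which the acquisition geometry aligns with the scan
direction -- hence axis-aligned ellipses suffice). Pixel coordinates are
0-based; a pixel belongs to the ROI when its center satisfies the ellipse
inequality with inclusive boundary. The per-fruit spectrum is the
arithmetic mean over ROI pixels, which commutes with calibration when the
reference frames are spatially uniform.

The analysis window keeps bands with 950 <= lambda <= 1650 nm, both
endpoints inclusive. The instrument grid bundled with the generator has
512 points on 900--1700 nm constructed so that exactly 421 fall inside the
window (46 points below, 421 uniform points at 5/3 nm spacing inside, 45
above). A uniform 512-point or 5 nm grid cannot produce a 421-band window;
the fixed documented grid preserves the 421-band geometry that all
downstream model dimensions depend on.

# SPXY partitioning

The calibration/prediction split uses sample-set partitioning on joint X--y
distances: d(i,j) = dX(i,j)/max dX + dy(i,j)/max dy with Euclidean spectral
distance and absolute response distance, followed by Kennard--Stone max--min
selection (seed with the maximum-distance pair; repeatedly add the
candidate whose minimum distance to the selected set is largest). The split
is run independently within each maturity stage so both sets represent all
stages at the requested 4:1 ratio (480/120 overall, 96/24 per stage).

Selection itself is deterministic; the configured seed (default 2) governs
only a pre-selection shuffle of within-stratum order, which fixes how ties
between duplicated points resolve (lowest index after the shuffle wins).
The y used in the joint distance is one designated target column (default
FI); one shared split serves all three regression targets and the
classifiers. Per-stratum calibration counts are rounded half-to-even, with
the last stratum adjusted so the global total matches the rounded global
ratio exactly.

# The regression models

## Multiscale CNN

Three parallel branches process the 421-band spectrum (as a 1-channel
sequence) at kernel scales 3, 5 and 7:

* small: two 3-kernels, channels 1 -> 16 -> 128, padding 1;
* medium: two 5-kernels, 1 -> 64 -> 128, padding 2;
* large: two 7-kernels, 1 -> 128 -> 128, padding 3.

Every convolution has stride 2 and is followed by batch normalization and
ReLU; each branch ends with 2x1 max pooling. For a 421-band input each
branch emits a 128 x 53 map (421 -> 211 -> 106 -> 53 by the standard length
formula), i.e. 6784 features when flattened. The branch maps are fused as

F_fusion = w1 * F_scale1 + w2 * F_scale2 + w3 * F_scale3,

where w1, w2, w3 are *learnable per-channel weight vectors* (length 128,
broadcast across positions), initialized to 1/3 and unconstrained. The
published description says only "learning weight vectors"; per-channel
weights are the natural reading between the scalar and per-element
extremes, and one-hot settings recover the single-branch networks exactly
(a property the tests assert). The fused map is flattened, passed through a
128-unit ReLU layer, and a final linear unit emits the prediction.

## Multiscale CNN--LSTM

The identical trunk produces the 128-dimensional fused representation
H_fusion; it is expanded to a length-1 sequence and passed through a
single-layer LSTM (input 128, hidden 128), whose hidden state feeds the
linear output. With one time step and zero initial state the forget gate
and the recurrent weights W_hh receive no gradient; W_hh is retained in the
parameter store (it is part of the architecture's parameter count) and
documented as inert. Both bias vectors of the LSTM receive identical
gradients for the same reason.

## ResNet18-1D

Stem Conv(1 -> 64, k7, s2, p3) + BN + ReLU + max-pool(k3, s2, p1), four
residual groups of two blocks each with channels 64/128/256/512 (3-kernels;
1-kernel projection shortcut whenever channels or stride change), global
average pooling to 512 features, and a linear head. For a 421-band input
the group lengths are 106/53/27/14.

## Training

Adam (learning rate 1e-4, beta 0.9/0.999), mean squared error, batch size
32. "Iterations" are epochs over the calibration set with seeded
without-replacement shuffling. Per-architecture defaults: 500 epochs with
early stopping for ResNet18-1D (10% internal validation holdout, patience
50, best weights restored -- the early-stopping strategy is named in the
protocol without parameters; these are the package's choices), 1000 epochs
for MSCNN, and the same 1000 for MSCNN--LSTM (its budget is unstated;
it inherits the trunk's). Bands are standardized per band with
calibration-set statistics stored in the model and re-applied at prediction
time. The optimization target is additionally z-scored internally and
back-transformed at prediction: with the learning rate fixed at 1e-4,
traversing the raw target scale (means around 8--15 N or %) would otherwise
consume most of a reduced epoch budget; predictions are always returned in
original units, so no interface or metric changes. Batch-norm uses
momentum 0.1 and epsilon 1e-5 (framework-conventional, echoed in the model
artifact); weights start from the seeded uniform fan-in scheme
U(-1/sqrt(fan_in), +1/sqrt(fan_in)).

The engine itself (forward, backward, Adam) is implemented in the package
in C++ single-precision with im2col/GEMM convolutions. Training is bitwise
reproducible for a fixed seed on a single thread. Tests validate the
forward pass against an independent layer-by-layer R recomputation and the
gradients against finite differences.

## Classical baselines

PLSR (default 10 latent variables; the count is not part of the published
protocol, and an internal seeded 5-fold cross-validation can select it
instead via \code{autoLv}), SVR with RBF kernel (C = 90, gamma = 1, on standardized bands),
and PCR (10 principal components, component signs fixed so the
largest-magnitude loading is positive, making refits bitwise identical).
For classification: PLS-DA (one-hot PLS projection; the class decision is
a Mahalanobis nearest-centroid rule on the latent variates -- with five
*ordered* maturity classes, argmax on raw indicator predictions is biased
against the middle classes and was observed to collapse their accuracy,
while the latent space itself separates the stages cleanly), SVM (C = 10,
gamma = "scale" i.e. 1/(B * var X) on standardized bands), and LDA with
recursive feature elimination (importance = aggregate absolute discriminant
coefficient; 10% of remaining bands dropped per iteration -- the published
protocol names RFE without a schedule, so the schedule is recorded in the
model artifact). RFE is not cosmetic for LDA: with 421 collinear bands and
~480 training spectra the pooled covariance is barely full rank and plain
LDA generalizes poorly; the study-design emulation keeps an 80-band budget
(about one RFE decade), which restores full separability. PLS and PCR are centered only; SVR, SVM and LDA
standardize bands, always with training-set statistics.

# Evaluation

RMSE = sqrt(mean squared residual); R2 = 1 − SSres/SStot about the
reference mean; RPD = SD(reference)/RMSE. The RPD uses the population SD
(divide by n) by default, which makes RPD = 1/sqrt(1 − R2) an exact
identity; the published benchmark table satisfies this identity to within
±0.01 on all 18 rows, which is how the convention was pinned down (the
sample-SD variant is available by flag). An RPD above 2.5 is the
conventional threshold for a reliable chemometric model. Stage summary
tables use the sample SD (n−1). Percent changes are rounded half away from
zero at one decimal.

Classification uses stratified five-fold cross-validation in which every
preprocessing step (standardization, RFE selection, latent projection) is
refitted inside each fold -- guaranteed structurally, because all
preprocessing lives inside the fit functions and sees only the fold's
training rows. Metrics (accuracy, macro precision/recall/F1, in percent)
are computed from predictions aggregated across folds; with the balanced
design, micro-averages equal accuracy, and macro-averaging is reported for
robustness. A guard test runs the selection-heavy LDA-RFE pipeline on
pure-noise labels and checks accuracy stays near chance.

# The synthetic generator

The generator is the package's stand-in for the (non-deposited) fruit
data; it emulates the *statistical and geometric structure* the pipeline
assumes, not radiative transfer. Per stage, FI and SSC are drawn from
truncated normal distributions with the study's stage means, SDs and ranges
(inverse-CDF sampling, exact), coupled by a Gaussian copula with
within-stage correlation −0.3 (softer fruit tends to be sweeter within a
stage; the true joint distribution is unknowable from summary statistics,
so this is a configurable package choice). FSR is computed per record, so
the FSR = FI/SSC identity holds by construction.

Each spectrum is a smooth scattering baseline whose offset (0.015 per N)
and tilt (0.006 per N) grow with firmness, minus Gaussian absorption dips:
fixed dips at 970 nm (O--H), 1080 nm (weak N--H) and 1270 nm (C--H), a
1200 nm dip with depth 0.010 x SSC (C--H sugar overtone), and a 1450 nm
water dip tied to a stage-linked moisture proxy with per-fruit jitter.
Structured nuisance (per-sample offset SD 0.010 and tilt SD 0.008) and
per-band Gaussian noise (SD 0.004, a typical InGaAs noise floor) make the
inverse problem nontrivial: the firmness signal lives in the same smooth
subspace as the nuisance, while the sugar signal is a local feature. The
nuisance and jitter amplitudes scale with the band-noise SD, so a single
noise parameter degrades everything monotonically and zero noise makes the
generator fully deterministic. Coupling strengths were chosen so the
generator meets its contract: high but imperfect held-out accuracy for the
deep regressors (R2 >= 0.8, RPD >= 2.0 at the desk scale) and full linear
separability of the five stages for PLS-DA/LDA, with any SVM confusion at
elevated noise confined to adjacent stages.

What passing tests on this generator do *not* show: performance on real
fruit, robustness to instrument drift, scatter effects beyond a smooth
baseline, or transfer across cultivars. The generator exists so the
pipeline's plumbing, conventions and learning dynamics are testable.

Synthetic cubes place an elliptical "fruit" with smoothly varying per-pixel
FI/SSC fields over a flat background (no sugar dip), and construct raw
digital numbers so that white/dark calibration recovers the intended
reflectance exactly; ground-truth maps accompany every cube.

# Numerical choices and degenerate inputs

* Band-window endpoints are inclusive on both sides.
* SPXY errors on all-identical X or y (the joint distance is undefined);
  duplicated points are fine and resolve by the seeded-shuffle tie rule.
* Max-min ties resolve to the lowest index; the seed pair orders (i, j)
  with i < j, scanning row-major.
* regressionReport treats perfect prediction as RPD = +Inf with an
  overflow flag; zero reference variance is a contract error.
* Stage summaries report SD = NA for singleton stages.
* The compiled engine computes in float32 (the field's standard precision
  for network training); forward-pass tests against the double-precision
  oracle use a 1e-4 tolerance, and training histories are bitwise
  reproducible per seed on one thread.
* Adam moments are re-initialized at each trainRegressor call; continuation
  training restarts the optimizer, not the weights.

# Problem sizes used by the test suite

The suite exercises the full 600-sample design: stratified SPXY to 480/120;
five-fold PLS-DA/LDA/SVM cross-validation on all 600 samples; and
MSCNN--LSTM training at a reduced budget of 200 epochs per target for the
three regression targets, with a 3-point noise-robustness sweep at a
further-reduced 40 epochs. Engine-correctness tests (forward oracles, gradient checks) run on
miniature configurations (16-band inputs, 2--5 channels) where the naive
double-precision recomputation is exact and fast.

# Known limitations

* The LSTM head sees a length-1 sequence, so its recurrent dynamics are
  inert by construction; it contributes a gated nonlinear transform of the
  fused features.
* SVR/SVM with the stated hyperparameters (gamma = 1 on 421 standardized
  bands) yields very localized kernels on high-dimensional spectra; the
  defaults reproduce the published settings rather than tuned optima.
* No scatter correction (MSC/SNV), smoothing, or wavelength selection is
  applied before regression: the pipeline models raw corrected reflectance
  by design, and such preprocessing is declared out of scope.
* Pixel-wise maps apply a point model to every pixel; averaging the map
  over a region equals the region-mean prediction only for linear models.
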