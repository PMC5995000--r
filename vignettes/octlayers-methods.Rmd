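---
title: "Methods: layer segmentation and tissue classification for cardiac OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer segmentation and tissue classification for cardiac OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlayers)
```

## The problem

Optical coherence tomography resolves the first 1–2 mm of the atrial wall at
micrometre scale, deep enough to see the tissue compositions that matter for
arrhythmia substrates: normal myocardium, loose and dense collagen, adipose
tissue and fibrotic myocardium. Reading these compositions off B-scans by hand
does not scale to volumetric datasets, and — unlike the retina — the atrial
wall has no fixed layer ordering or thickness that a segmentation algorithm
could assume. `octlayers` implements a pipeline that makes no structural
assumptions: it first discovers how many layers a B-scan contains and roughly
where they are, then localizes each boundary column by column, summarizes
every layer with 16 optical/statistical/texture features, and classifies each
layer with a sparse Bayesian (relevance vector machine, RVM) classifier.

Because matched human-heart/histology data are not shippable, validation is
built on a synthetic phantom generator whose ground truth is exact by
construction. The phantom module is first-class, tested code, not a fixture.

## Pipeline

### Preprocessing

B-scans are linear-intensity grids indexed `[z, x]` (row 1 = shallowest).
Coordinates are 1-based throughout, and layer k occupies the half-open row
band `[upper, lower)` at each column.

1. **Denoising.** OCT speckle is multiplicative; the default denoiser is a
   5×5 median filter. BM3D is supported as a plug-in
   (`options(octlayers.bm3d = fn)`) and requesting it without a registered
   implementation is an explicit error, never a silent substitution. The
   median filter runs on a log-compressed copy of the image: the median
   commutes with monotone transforms, so the result is the same median, but
   computed at uniform *relative* precision — OCT intensities span several
   decades and a fixed-resolution filter on the linear scale would crush the
   deeply attenuated signal to zero.
2. **Surface detection.** In atrial OCT the endocardial surface is the most
   hyper-reflective structure, so on every retained A-line the surface is
   the intensity argmax along depth (ties → shallowest row). A-lines are
   retained every `downsample_factor` (default 10) columns, each as the mean
   of its column block (antialiased downsampling), and the full profile is
   linearly interpolated. Because the true surface varies smoothly, a
   retained position deviating more than 15 px from the running median of
   its neighbours (an occasional bright deep granule under speckle) is
   discarded and refilled by interpolation. Noise-free detection at full
   sampling is exact; the argmax systematically sits mid-way into the
   specular band, giving a ~2 px deep bias under speckle at default
   settings.
3. **Flattening.** Each column is shifted by an integer so the surface lands
   on the rounded median surface row; vacated rows are filled with the
   column minimum. Flattening only shifts, so every A-line keeps its
   multiset of in-tissue values, and it keeps the subsequent per-column
   search range small.

### Layer-information estimation

Five A-lines are taken around the image centre, 200 µm apart, each the mean
of 20 neighbouring A-lines; lateral averaging in linear intensity suppresses
speckle before the profile is log-transformed. In log intensity the
single-scattering decay inside one layer is a straight line, so layer
boundaries appear as slope breaks.

Each averaged profile is broken into linear pieces by a growing-window
least-squares fit: starting just below the profile maximum (the specular
surface peak; the first window is offset `skip_below_anchor = 6` px so the
peak does not pollute the first piece), a window of 10 px is extended 3 px
at a time while the fit's RMSD stays below a threshold; when it exceeds the
threshold the window end is recorded as a *changing point* and a new anchor
starts one window beyond it. A break recorded within one initial window of
the profile end is discarded — there is no room to fit another layer there.

The RMSD threshold is the one tunable without a stated value; it is
expressed as a fraction of each profile's dynamic range so that it transfers
across imaging depths. The packaged default, 0.06, was chosen with
`scripts/calibrate_threshold.R`, which sweeps the fraction over noise-free
and speckled 2–4-layer phantoms: fractions of 0.05–0.06 vote the correct
layer count on 100 % of calibration seeds in both regimes, with failure on
either side (over-segmentation below, merged layers above).

Changing points closer than 30 px are merged at their midpoint (rounding
half-down), and points near the anchor whose local standard deviation
exceeds 1.5× the profile-wide one are deleted (specular-peak artifacts; the
window and factor are declared defaults, 10 px and 1.5). The per-A-line
layer counts are then pooled: the global count is the modal count with ties
broken toward *fewer* layers (under-segmentation is recoverable downstream;
spurious boundaries are not), and each initial boundary point is the median
across the A-lines that voted for the winning count.

### Boundary search

Boundary pixels should have a high positive axial gradient, high intensity,
and lie near the initial changing points. The cost is

c(x, z) = c1·g(x, z) + c2·i(x, z) + c3·p(x, z),  c1 + c2 + c3 = 1,

with default weights (0.56, 0.38, 0.06). Both `g` (positive part of the
axial backward difference) and `i` are computed on the log image and
rescaled per-image to [0, 1] so the printed weights are meaningful across
inputs; `p` is a triangular prior equal to 1 at each initial point, decaying
linearly to a floor of 0.1 midway between adjacent points (30 px half-width
outside the outermost points). Whether to normalize before weighting was an
open choice; per-image min–max rescaling is the declared one, and the
weights remain user-tunable.

Each boundary is traced greedily from the centre column outward: at every
new column the row is the cost argmax within ±Δz (default 5 px) of the
previous column's row, ties toward the shallower row, windows clipped at the
image edge. The greedy scan is the method; an exhaustive
dynamic-programming path solver exists only in the test suite as an oracle,
where the two provably coincide on maps with a unique bright non-crossing
path of bandwidth ≤ Δz. After the per-boundary searches (which run
independently), non-crossing is enforced by clamping
(`boundary_k + 1 ≤ boundary_{k+1}` per column); a boundary that collapses
onto its neighbour over more than half the columns is merged away with a
warning.

### Features

Every layer is summarized by exactly 16 features, in a frozen order
(`FEATURE_NAMES`): mean/SD of per-A-line attenuation coefficient and
penetration depth, mean/SD of local (3×3) standard-deviation and range
filters, histogram entropy, TCN coarseness and homogeneity, GLCM contrast
and energy, distance from layer centre to the surface, skewness and
kurtosis.

* **Attenuation** uses the round-trip single-scattering model
  `I(z) = I0·exp(−2µz)`: µ is −slope/2 of the least-squares log-linear fit,
  per A-line on the rows inside the layer at that column (columns with < 5
  in-layer rows are skipped). The estimator is pluggable; the log-linear fit
  is the declared implementation.
* **Penetration depth** is the first (linearly interpolated) depth at which
  intensity falls to 1/e of the segment-start value, measured from the layer
  top (not the tissue surface — a declared reading of an ambiguous
  definition), with a flag when never reached.
* **Statistical/texture features** are computed on a histogram-equalized
  (256 levels), median-filtered (3×3) crop of the layer, statistics
  restricted to the in-layer mask. Entropy uses 256 bins, base-2 logarithm.
  Kurtosis is non-excess (normal → 3).
* **TCN** codes each pixel by the intensity relation to its eight
  neighbours, clockwise from north, one ternary digit each (below / within /
  above a tolerance ε, default 2 % of the equalized range): codes lie in
  [0, 3^8). Homogeneity is the sum of squared code frequencies; coarseness
  the mean fraction of "within ε" neighbours.
* **GLCM** quantizes to 16 levels over the region range, counts horizontal
  (offset (0, 1)) in-mask pairs, symmetrized. Contrast and energy enter the
  feature vector; correlation is also computed but deliberately excluded
  from the 16-entry vector and attached as metadata
  (`attr(fv, "glcm_correlation")`) — the classifier consumes exactly 16
  features, and correlation is the one texture score that did not make the
  frozen list.

### Relevance vector machine

For a binary problem, `p(c = 1 | x) = σ(Σ w_i φ_i(x))` with one kernel basis
per training point plus a bias, and an individual zero-mean Gaussian prior
`N(w_i | 0, α_i⁻¹)` per weight. Training alternates:

1. **Newton/IRLS inner loop** to the mode of the penalized Bernoulli
   log-likelihood: `∇E = Aw − Φᵀ(c − σ(Φw))`, `H = ΦᵀBΦ + A` with
   `B = diag(σ_n(1 − σ_n))`, `A = diag(α)`, damped steps (step-halving on the
   objective), run to `‖∇E‖ < 1e−6`.
2. **MacKay evidence update** `α_i ← γ_i / w_i²`, `γ_i = 1 − α_i Σ_ii` with
   `Σ = H⁻¹` at the mode. Weights whose α reaches 1e12 are pruned (the bias
   never is); the surviving training points are the relevance vectors.

The outer loop stops when `‖Δw‖ < 1e−4` (500 iterations maximum).
Initialization is `α = 1`, `w = 0`; features are standardized with training
statistics only. The kernel default is RBF with the median-pairwise-distance
width — both unstated in the original setting and exposed in the
configuration. Five-class decisions use one-vs-rest submodels and the argmax
of the per-class probabilities (ties → alphabetical). The prior is read as
the standard per-weight diagonal `A = diag(α_i)`. Since no installed package
provides a classification RVM, the test oracles are a numerical optimizer
(for the Newton mode) and 1-D quadrature of the exact marginal likelihood
(for the α fixed point) on toy problems.

### Volumes, evaluation, rendering

Across a volume, each boundary is a surface over (B-scan, column) and is
median-filtered with a (3, 5) kernel (the filter size being a declared
default), after which ordering is re-clamped; classification can be re-run
on the smoothed regions. Leave-one-group-out evaluation trains on all groups
but one (a group models one donor heart or one phantom seed), scores
layer-wise, and aggregates a 5×5 confusion matrix in `TISSUE_CLASSES` order.
Renders encode class as hue (dense collagen gold, loose collagen yellow,
normal myocardium red, adipose blue; fibrotic myocardium magenta — chosen
here because trichrome shows fibrosis as purple and the original four-hue
palette left it unassigned) with saturation and value tracking normalized
intensity.

## The phantom generator

Phantoms are the study conditions, not a tuning dial. Defaults mirror the
target system's geometry: 800×512 px per B-scan at 5 µm lateral / 4.9 µm
axial spacing (4 mm × 2.51 mm). Each layer decays exponentially below its
own top with its class's attenuation, modulated by a texture field:

| class | base intensity | µ (mm⁻¹) | texture |
|---|---|---|---|
| normal myocardium | 0.80 | 2.5 | granular, 2 px |
| loose collagen | 0.45 | 1.2 | smooth |
| adipose | 0.60 | 1.8 | honeycomb, 12 px cells |
| fibrotic myocardium | 0.70 | 3.2 | granular, 5 px |
| dense collagen | 0.95 | 4.5 | smooth |

These presets are the package's single declared choice of "realistic": dense
collagen bright and strongly attenuating, loose collagen dim and weakly
attenuating, adipose honeycombed (bright cell walls around dark interiors on
a jittered hexagonal lattice), the two myocardium classes intermediate with
different grain. Speckle is unit-mean multiplicative exponential noise
(`S = 1 + noise_scale·(E − 1)`, `E ~ Exp(1)`), fully developed at the
default `noise_scale = 1`; the instrument's actual noise statistics are
unknown, so SNR is a free parameter, not a calibration. A 5 px specular band
of intensity 2.0 marks the surface — the Fresnel reflection at the
saline/endocardium interface that makes argmax surface detection physically
sensible; without it, a deep layer more reflective than the attenuated
surface layer would defeat *any* brightest-pixel detector. Surfaces may be
flat, tilted or sinusoidal, with slow drift across B-scans; all randomness
flows through one seeded generator per B-scan.

What the phantoms deliberately omit: the confocal PSF and sensitivity
roll-off, refraction, blood vessels and other circular inclusions, noise
floors, and cross-heart intensity variation. Passing phantom tests therefore
demonstrates the algorithmic chain (geometry recovery, feature fidelity,
classifier behaviour), not instrument-level performance on human tissue.

## Numerical choices and degenerate inputs

* Boundary positions are real-valued; rasterization rounds half-up.
* A zero-variance region returns skewness 0 / kurtosis 3 with a flag;
  single-level GLCM returns contrast 0 / energy 1 with correlation flagged
  NA; nonpositive intensities in a log fit are floored at machine epsilon
  with a warning; an all-zero A-line's surface is interpolated from
  neighbours with a warning.
* Argmax and search ties always resolve to the shallower row; vote ties to
  the smaller layer count; classification ties alphabetically.
* Problem sizes used by the validation suite: 20 seeds at 800×512 for
  boundary recovery, 60 + 30 segmentations for layer counting, 200-point
  leave-one-out for the RVM, 20 groups (~100 layers) for the five-class
  end-to-end run.

## Known limitations

* The greedy column scan has no global optimality guarantee off the easy
  regime; a drifting start point biases a few columns near the image centre.
* Layer counts are global per B-scan; images whose layer count changes
  laterally are approximated by the modal structure.
* The classifier is only as transferable as the features; phantom-trained
  models should not be applied to real tissue.
* BM3D parameters are whatever the plugged-in implementation uses; the
  package records which denoiser ran but does not validate its settings.
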