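---
title: "Quantifying macrophage polarization from cell painting images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrophage polarization from cell painting images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Macrophages adopt activation states along a continuum whose extremes are
the pro-inflammatory M1(-like) state — round, flattened cells — and the
anti-inflammatory M2(-like) state — elongated cells; M0 denotes the
unstimulated state. In high-content screening, four-channel cell painting
images (Hoechst33342 for nuclei, Alexa488 concanavalin A for ER/cytoplasm,
and two further organelle stains read out as Alexa568 and Alexa647) carry
enough morphological and textural information to identify and quantify
compound-induced (re-)polarization. `cellpaintr` implements the full
analysis chain:

1. plate I/O (16-bit TIFF fields, JSON plate maps, CSV/parquet tables);
2. a seeded synthetic-plate simulator with known per-well class mixtures;
3. flatfield correction, nucleus detection and nucleus-seeded cell-body
   segmentation with border exclusion;
4. a 1279-entry per-cell feature catalog over three regions;
5. the cell-roundness Z-score read-out against DMSO vehicle wells, with
   cell-count toxicity flagging;
6. per-well profiles, standardization and 2-component PCA fingerprints;
7. a sparse pairwise linear classifier yielding per-well %M0/%M1-like/
   %M2-like and the DMSO-normalized %M2(-like)−%M1(-like) score, with
   relevant-feature reports and morphology-ablation variants;
8. a compact four-class CNN (M0, M1-like, M2-like, dead) with a 40%
   confidence gate, well-level ratios and replicate averaging, compared
   with the feature-based scores by Pearson correlation.

## The synthetic plate simulator

No public imaging data accompany this assay, so every stage is exercised
on simulated plates whose ground truth is known exactly.

Cells are rotated super-ellipses (exponent 2.5) with a low-order radial
boundary perturbation, rasterized onto the field grid, and lightly
Gaussian-blurred (sigma 1 px, replicate boundary). The nucleus is a
rounder concentric ellipse occupying a fixed area fraction of the cell.
Channel logic follows the assay: Hoechst signal only in the nucleus,
Alexa488 filling the cell body, Alexa568/Alexa647 filling the cell body
modulated by a smooth multiplicative texture field. A multiplicative
second-order (radial quadratic) illumination surface, additive Gaussian
noise and optional Poisson resampling complete the camera model; grids
are quantized to 16-bit counts.

The class regimes are the package's study conditions:

| class  | aspect ratio | area (µm²) | signature |
|--------|--------------|-----------|-----------|
| M0     | 2.0 ± 0.2    | 450 ± 70  | baseline intensities |
| M1-like| 1.1 ± 0.08   | 420 ± 65  | round; bright Alexa568 |
| M2-like| 3.0 ± 0.3    | 480 ± 75  | elongated; bright Alexa647 |
| dead   | 1.1 ± 0.08   | area ×0.35 | nucleus intensity ×2, cytoplasm ×0.3 |

The aspect-ratio means (M1-like ≈ 1.1, M0 ≈ 2.0, M2-like ≈ 3.0) realize
the round-vs-elongated morphology axis; the published record gives no
quantitative shape statistics per condition, so these values are
tool-chosen and documented here rather than presented as measured
biology. Intensities (counts above a baseline of 100): Hoechst 3000,
Alexa488 1500 for all live classes; Alexa568 is 800/2200/600 and
Alexa647 800/600/2200 for M0/M1-like/M2-like, so shape *and* intensity
are informative — the regime in which morphology ablation is expected to
leave the read-out intact. The dead phenotype (small cells, condensed
bright nuclei, dim cytoplasm) stands in for a staurosporine-treated
training condition. Defaults elsewhere: 1080×1080 px fields at
0.6 µm/px (a 20×, binning-2 geometry), 50 cells per field.

Class mixtures per well are realized *exactly* by largest-remainder
apportionment and spread round-robin over fields, which makes
mixture-recovery tests sharp. Placement is rejection sampling against an
exact occupancy mask (400 retries), with a deterministic shuffled
grid-scan fallback for crowded fields. Everything is a pure function of
(seed, config, plate map): identical seeds give bit-identical plates.

What the simulator does **not** emulate: cell–cell contact and clumping,
spectral bleed-through, photobleaching, focus drift, debris, or 3D
structure. Consequently, passing tests demonstrate that the analysis
machinery is correct and internally consistent — not that its accuracy
numbers transfer to real microscope data.

## Segmentation

Per field: (i) flatfield correction, (ii) nucleus detection on Hoechst,
(iii) cell-body segmentation on Alexa488, (iv) region derivation.

*Flatfield.* The illumination surface is estimated as a second-order
polynomial fitted (least squares) to background-like pixels — pixels
above twice the field median are treated as foreground and excluded from
the fit. The image is divided by the surface and rescaled to preserve its
mean. A polynomial fit was chosen over heavy Gaussian smoothing of the
raw field because smoothing drags cell signal into the surface estimate;
on simulated fields with a known quadratic artifact the fitted surface
restores the unshaded image to well under 2% (after matching overall
brightness), where smoothing-based estimates leave several percent of
residual shading.

*Nuclei.* Gaussian smooth (sigma 2 px) → Otsu threshold on
log-compressed intensity → fill holes → distance-transform watershed to
split touching nuclei → area filter (default 50 px, rejecting debris
while keeping shrunken dead cells) → optional removal of border-touching
objects. The log compression matters on dead-cell-rich fields: very
bright apoptotic nuclei otherwise pull the Otsu threshold above the dim
unstimulated nuclei. Labels are relabeled 1..K in deterministic
(first-pixel) order.

*Cell bodies.* Nucleus-seeded propagation (`EBImage::propagate`) on the
smoothed Alexa488 channel, with the foreground mask from Otsu always
augmented by the nucleus pixels — a nucleus with no surrounding signal
degenerates gracefully to cell = nucleus. Cell labels equal their
nucleus labels by construction.

*Regions.* Per cell: `nucleus`, `cytoplasm` = cell \\ nucleus (possibly
empty), `cell`. The set identities hold exactly and are asserted by the
constructor.

## The 1279-entry feature catalog

The published total of 1279 features is reproduced by a documented
decomposition (the original itemization is proprietary):

* per channel × region (4 × 3 = 12 combinations), 105 features each:
  * 13 intensity statistics: mean, sd, CV, median, MAD, min, max, sum,
    5%/95% quantiles, skewness, excess kurtosis, and background-corrected
    integrated intensity (sum − field background median × area);
  * 32 SER texture features: 8 properties × 4 scales (1, 2, 4, 8 px; the
    assay's published scale 2 among them);
  * 24 Gabor features: 3 carrier periods (16, 8, 4 px) × 4 orientations
    (0°, 45°, 90°, 135°) × 2 statistics (mean magnitude, energy);
  * 36 STAR features (below);
* 5 standard morphology properties × 3 regions = 15 (mask-based,
  channel-independent): area, roundness, width, length, width/length;
* 4 context features: nucleus/cell area fraction, nucleus displacement,
  neighbour count within 30 µm, distance to the field border.

12 × 105 + 15 + 4 = **1279**. `enumerate_catalog()` is a pure function
of the configuration, and the sidecar JSON written next to feature tables
is the machine-readable twin of the list.

The Gabor bank uses four orientations at multiples of 45° (rather than
three) so that rotating an image by 90° permutes the orientation-indexed
features exactly — a property the test suite checks; the 3-period ×
4-orientation layout preserves the 24-feature count.

*SER responses* are scale-normalized Gaussian-derivative / Hessian
-eigenvalue maps (eigenvalues λ₁ ≤ λ₂ of the smoothed Hessian): spot =
(−(λ₁+λ₂))₊ (bright Laplacian blob), hole = (λ₁+λ₂)₊, edge = gradient
magnitude, ridge = (−λ₁)₊, valley = (λ₂)₊, saddle = √((−λ₁)₊·(λ₂)₊),
bright/dark = rectified deviation from the local Gaussian mean. Each is
averaged over the region and divided by the region mean intensity
("kernel normalization"), making every SER feature invariant to positive
rescaling of the image and zero on constant images. These are
tool-defined analogues, not reproductions of any vendor's numeric values.

*Gabor features* come from quadrature (even/odd) pairs with an isotropic
Gaussian envelope (σ = 0.56/f), mean-subtracted so constants map to
zero; mean magnitude is normalized by the region mean intensity and
energy by its square.

*STAR features* are intensity-weighted shape descriptors computed after
sliding-parabola background removal — a grayscale opening with a
parabolic structuring element (default radius 10 px, between the texture
scales and the cell size; parabola depth tied to the image's robust
dynamic range), implemented as separable 1D min/max sweeps. On the
background-removed intensity restricted to the region: 12 symmetry
scores 1/(1+|m|) from reflection-odd normalized central moments in the
principal frame (all equal to 1 for radially symmetric signal); 12
threshold-compactness features (support compactness, area fraction and
intensity fraction at four quantile thresholds — at quantile 1.0 the
support is the full region, so its compactness equals the region's
roundness); 4 axial features (elongation, skews along both axes,
|correlation|, all ≈ 0 for radial signal); 4 radial-distribution and 4
radial-profile features. Two numerical safeguards keep these stable:
near-isotropic regions (eigenvalue gap below 10⁻⁸ of the trace) snap the
principal frame to the grid axes, and radial shell binning rounds away
floating-point jitter at shell boundaries.

*Morphology* is mask-based: area (µm²), roundness = 4πA/P² clamped to
[0, 1] with a 4-direction Crofton perimeter estimate (lower rasterization
bias than boundary-pixel counting), and width/length as the minor/major
axis lengths of the second-moment equivalent ellipse. A single-pixel
region is defined as roundness 1 with unit axes.

*Sentinels.* An empty cytoplasm (nucleus fills the cell) yields zero
intensity/texture features and inherits the nucleus morphology, so
feature tables never contain missing values.

## Cell-roundness Z-score

Per well, the mean full-cell roundness over retained cells; per plate,

Z = (well mean roundness − mean of vehicle-well means) / sd of
vehicle-well means,

with the sample (n−1) standard deviation. Z > 0 indicates a more rounded
(M1-like) population, Z < 0 a more elongated (M2-like) one. The score is
computed at the *well* level — well means are the statistical units,
matching how replicate dispersion is reported for this assay — rather
than per cell; with small vehicle-well counts the sample sd is the
appropriate scale. Two immediate consequences are used as exact
self-checks: vehicle wells scored against themselves have mean 0 and
sample sd 1, and Z is invariant to any affine rescaling of all roundness
values on the plate. At least two vehicle wells with cells are required;
empty wells are excluded and flagged.

Toxicity: wells with fewer cells than half (configurable) the median
vehicle-well count are flagged. Cytotoxic conditions can masquerade as
rounded (M1-like) phenotypes, so the flag is reported alongside scores,
and classified cells from toxic wells are *not* filtered out.

## Profiles and PCA

Well profiles are arithmetic means of each feature over the well's
cells. Standardization centers by the mean and scales by the sample sd;
zero-variance columns cannot be scaled and are dropped (logged).
`pca2()` returns the first two principal components with a deterministic
sign convention (largest-magnitude loading positive). Rank-1 input
(points on a line) is valid — PC1 explains 100% and PC2's ratio is 0;
only fully degenerate zero-variance input errors. Explained variance
ratios are descending and sum to ≤ 1.

## The linear classifier

Training cells are drawn seeded, without replacement, exactly
`cells_per_class` per state (default 100), stratified round-robin across
the source wells. The discriminant is one-vs-one L1-regularized logistic
regression (glmnet) on features standardized over the training cells,
with a fixed regularization strength (default λ = 0.02 on standardized
features) — small enough to keep the informative features, large enough
that each pair's model is sparse, so the nonzero coefficients *are* the
per-pair "relevant features" report. The proprietary classifier this
stands in for is linear with per-pair feature relevances; the surrogate
reproduces those observable outputs without claiming internal parity.

Prediction: three pairwise votes; majority wins; ties broken by summed
signed margins, then by the fixed class order M0 < M1like < M2like.
Per-well percentages are computed over classified cells and sum to 100;
the polarization effect size is

normalized_score = (%M2like − mean %M2like over vehicle wells) −
(%M1like − mean %M1like over vehicle wells),

which averages exactly zero over the vehicle wells of any plate. Models
serialize to JSON and reload with bit-identical predictions.

`ablation_compare()` retrains on the *identical* sampled cells with the
three masks (all features; without the 15 standard morphology features;
without only the full-cell roundness feature) and tabulates the scores
side by side with pairwise Pearson correlations. Under the simulator's
default regime (shape and intensity both informative) the all-features
and no-roundness scores correlate essentially perfectly — the read-out
does not hinge on roundness, while roundness remains a relevant feature
for separating M0 from M1-like.

## The CNN

Per-cell crops (default 64×64 px, 4 channels, centred on the nucleus
centroid, zero-padded at field borders) are normalized to [0, 1] by
plate-level 1st/99th intensity percentiles. The classifier is a compact
seeded network — average-pool 2, conv 5×5 (4→8) + ReLU, max-pool 2,
conv 3×3 (8→16) + ReLU, max-pool 2, dense 576→32 + ReLU, dense →4,
softmax; ≈ 21k parameters — implemented directly on BLAS matrix products
(im2col convolutions) with Adam and cross-entropy, trained per run on
simulated crops (no shipped weights). Training and inference are
deterministic given the seed, and a few hundred crops per class train in
well under a minute per epoch on one CPU core.

Confidence is the maximal softmax probability; predictions below the
threshold (default 0.40) are excluded from all downstream ratios, and
the excluded count is reported. Raising the threshold can only shrink
the retained set (monotonicity). Well-level ratios over retained cells
sum to 1; condition-level values are unweighted means over replicate
wells. The cross-tool check correlates condition-level DMSO-normalized
100·(ratio_M2like − ratio_M1like) from the CNN with the linear
classifier's normalized scores (Pearson).

## Numerical conventions and degenerate inputs

* MAD is the raw median absolute deviation (constant 1); sd is the
  sample (n−1) convention throughout (intensity features,
  standardization, Z-score); skewness/kurtosis are population moments.
* Quantiles use R's default type 7.
* Watershed/label ties and relabeling are deterministic; all stochastic
  stages derive their seeds from one run seed by stable string hashing,
  so no seed bookkeeping is needed and reruns are bit-identical.
* Channel names are a closed set; unknown names are rejected at parse
  time. A field missing a channel is a hard error naming the field.
* Zero cells in a well: excluded and flagged, never silently imputed.

## Problem sizes

The test and benchmark runs use deliberately desk-scale conditions,
stated here as the package's own benchmark choices: 256×256 px fields at
0.6 µm/px with 12–14 cells per field; a 56-well benchmark plate (4 DMSO
vehicle wells, 8 pure wells per polarization class, 4 dead-cell wells,
12 mixture conditions × 2 replicate wells); 100 training cells per class
for the linear classifier; 12 CNN epochs on ~400 crops; 20 seeded plates
for the Z-score sign-recovery experiment. `scripts/acceptance.R` re-runs
all of these from scratch.

## Known limitations

* Segmentation is tuned to the simulator's regime (non-touching,
  well-stained cells); real plates with confluent or clumped macrophages
  would need the watershed and propagation parameters revisited.
* SER/STAR definitions are tool-defined analogues; absolute feature
  values are not comparable with any commercial implementation, though
  family structure, normalization and invariances match.
* The CNN is intentionally small and trained on synthetic data only; it
  demonstrates the contract (four classes, confidence gating, replicate
  averaging), not state-of-the-art accuracy on real images.
* Cross-plate batch effects and harmonization are out of scope; all
  normalization is within-plate against DMSO vehicle wells.
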