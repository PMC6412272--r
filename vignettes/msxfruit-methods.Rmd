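---
title: "Fruit recognition in MSX pseudo-color images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fruit recognition in MSX pseudo-color images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msxfruit` detects apple fruit regions in pseudo-color thermal canopy images
produced by multi-spectral dynamic imaging (MSX) cameras. This vignette
explains the model behind each stage, the tunable parameters and their
defaults, the numerical conventions, what the synthetic-data generator does
and does not emulate, and the limitations that follow.

## The physical signal

Fruit store and release heat more slowly than leaves and twigs, so under
changing sunlight a fruit's surface temperature separates from its
surroundings. In a warm display palette the fruit renders orange — a high
red channel — while foliage and sky render cooler. MSX imaging additionally
embosses visible-light edge detail onto the thermal raster, so surface
*texture* is visible: fruit surfaces are smooth, while foliage, bark and
soil are rough. The detector uses both cues in sequence: color gets
candidate regions cheaply; texture separates fruit from warm-but-rough
confounders such as sunlit soil.

## Pre-processing

Candidate extraction runs entirely on the red channel:

1. **Red-component grayscale.** `to_red_gray()` projects the H×W×3 raster
   onto its red channel. No luminance mix is used: in the warm palette the
   red component alone carries the fruit/background contrast.
2. **Otsu binarization.** `otsu_threshold()` maximizes the between-class
   variance σ²_B(t) = ω₀(t)ω₁(t)(μ₀(t) − μ₁(t))² over the 256-bin
   histogram. Conventions: foreground is `pixel > t` (fruit are bright;
   a `binarize_polarity` option inverts this for other palettes); ties are
   broken toward the lowest maximizing t; a constant image is flagged
   degenerate with t equal to the constant, yielding an empty mask.
3. **Morphological opening.** `morph_open_disk()` erodes then dilates with
   a disk structuring element — all integer offsets with Euclidean norm
   ≤ radius. Pixels outside the image count as background; opening is
   idempotent and anti-extensive under this convention. The default radius
   is 3 px at the 400×300 working scale: large enough to delete salt noise
   and thin bright edges, small enough that a 12 px-semi-axis fruit
   survives essentially intact. Note that *discrete* disks are not exactly
   open with respect to smaller discrete disks, so even a clean disk may
   lose a few boundary pixels.
4. **Small-area removal.** `remove_small_regions()` computes the largest
   component area A_max and keeps exactly the components with area
   *strictly greater* than A_max/10 (fraction configurable in (0, 1]).
   The strict inequality follows the rule's phrasing ("larger than");
   a component at exactly the threshold is dropped.
5. **Labeling.** Components are labeled under 8-connectivity by default
   (4 available), with labels assigned in raster-scan order of each
   component's first pixel, making label maps reproducible bit-for-bit.
   Border-touching regions are kept: fruit at the image edge are
   legitimate targets.
6. **Color restoration.** The original pseudo-color values are restored
   inside the cleaned mask, zero elsewhere, so the texture stage sees the
   real surface detail of each candidate.

## Texture features

Each region is cropped to its minimum bounding rectangle, which keeps the
constant zero background as small as geometry allows. The red-channel patch
is quantized to L = 16 levels by uniform binning (`q = floor(v·L/256)`);
16 levels keep co-occurrence matrices well populated even for regions of a
few hundred pixels.

Gray-level co-occurrence matrices are built at pixel distance d = 2 along
0°, 45°, 90° and 135° (offsets (0,2), (−2,2), (−2,0), (−2,−2); diagonal
steps are *not* unit-normalized), symmetrized by counting both orderings,
and normalized to sum 1. Three Haralick features are computed per direction
and averaged arithmetically:

* **contrast** Σ (a−b)² p(a,b) — depth of the texture groove;
* **entropy** −Σ p log₂ p — heterogeneity of the co-occurrence
  distribution (base 2 by default; the base rescales but never reorders);
* **correlation** Σ (a−μ_r)(b−μ_c) p(a,b) / (σ_r σ_c), defined as 0 when a
  marginal has zero variance.

Zero background pixels inside the rectangle *are* counted by default — the
minimal rectangle is the mitigation, and masked-pair counting is available
via `glcm_masked = TRUE`. A region with no valid pixel pair in any
direction (e.g. a single pixel) is flagged degenerate, gets features
(0, 0, 0), and is later classified non-fruit without model evaluation.

Why these two defaults features: on smooth shaded fruit, co-occurrences
hug the diagonal across several levels (low contrast, spread-out
distribution, higher entropy); on rough speckled surfaces, mass sits in a
few far-off-diagonal cells (high contrast, concentrated distribution,
*lower* entropy — each region carries a dark zero-background share, and
the speckle's two tones make the soil distribution more homogeneous than
the fruit's). Correlation discriminates poorly between the two classes and
is dropped from the default feature vector, though it is always computed
and reported; `feature_set` can re-enable it.

## Classification

Regions are classified by the linear decision function
f(xᵢ) = sign(ω*·xᵢ + b*) with the tag convention −1 = fruit,
+1 = non-fruit (kept exactly as the field's convention for this detector;
the semantics live in the label, not in a remapping). Features are
standardized to zero mean and unit spread before optimization — contrast
and entropy live on very different scales — and the standardization is
stored in the model, making predictions invariant to affine rescaling of
the raw features.

The maximum-margin separator is found with a soft-margin linear SVM at a
large penalty (C = 1e4): hard-margin in effect on separable data (training
accuracy 100%, margins y(ω·x̃+b) ≥ 1 − 1e-6), while near-separable data
still train with a reported error instead of failing. The quadratic solver
starts at a tight termination tolerance (1e-8) and relaxes it stepwise to
at most 1e-2 if it hits its iteration cap — which happens precisely when
the large penalty meets clearly non-separable data, where the tight
tolerance buys nothing. The tolerance actually used is stored in the
model. `sign(0)` maps to −1 (fruit), a measure-zero tie documented rather
than randomized. Models serialize to JSON with their feature order,
standardization, weights, bias and training metadata.

## Evaluation

A predicted mask is compared with manual per-fruit masks through four
pixel counts: S_ic (correct inside the manual region), S_il (leakage:
manual pixels missed), S_oc (correct outside), S_oo (over-segmentation).
They always partition the image. The metrics are RP = S_ic/(S_ic+S_oo),
RS = S_ic/(S_ic+S_il), RE = (S_oo+S_il)/(S_ic+S_il), with the algebraic
identity RS + RE = 1 + S_oo/(S_ic+S_il) (so RS + RE ≥ 1 always). When
nothing is detected for a region, RP is defined as 0 and flagged.

For per-region reporting, every predicted pixel is attributed to one
manual region — its own if inside one, otherwise the nearest by Euclidean
distance to region support, ties to the lower region id. This generalizes
whole-image pooling (also available via `pooling = "image"`) to a
per-region decomposition. Summary rows are unweighted arithmetic means of
per-region metrics, stratified into complete vs. incomplete fruit regions;
the category is a ground-truth annotation (occlusion or overlap), never
inferred from the masks.

## The synthetic-scene generator

Real orchard MSX photographs are rarely shareable, so the generator
produces scenes that reproduce the *statistical contrasts* the detector
relies on, with exact ground truth:

* **Background:** cool palette (mean red 70), value noise with ~3 px
  correlation length plus fine grain — rough at GLCM scale.
* **Fruit:** 2–10 ellipses per scene (semi-axes 12–30 px), warm palette
  (center red 245 shading radially to ~190) with low-amplitude smooth
  noise — the quantized patch spans several gray levels smoothly.
* **Branch occluders:** with probability 0.45 a fruit is crossed by a
  cool-colored cap covering 8–35% of its visible area, cut by a chord so
  the remainder stays connected. Manual masks *include* the hidden pixels
  (an annotator knows the fruit continues behind a thin branch), which is
  what drives sensitivity below 1 for incomplete regions.
* **Overlap:** fruit may overlap (a front fruit owns shared pixels, and a
  candidate placement is rejected if it would hide more than 45% of any
  placed fruit); overlapping fruit are annotated incomplete.
* **Soil confounder:** one ellipse with fruit-like mean color but a
  two-tone speckle (red tones ±44 around 214), placed at least 8 px from
  any fruit. Its quantized red channel alternates between two distant
  levels: high contrast, low entropy — fruit-colored but texture-distinct,
  so scenes are separable by (contrast, entropy) but not by color alone.
* **Noise:** Gaussian σ = 5 per channel, clipped to [0, 255].
* 10% of fruit may touch the image border (border-handling exercise);
  scenes are bit-identical given the same seed, and annotations
  (occluded fraction, overlap, complete/incomplete, target under the
  60%-occlusion rule) are recomputable from the stored masks.

What the generator does **not** emulate: thermal physics (temperature
contrast is modeled directly as color contrast), camera optics and palette
quantization artifacts, JPEG compression, leaf clutter with intermediate
temperatures, wind-blurred edges, or fruit clusters of more than a few
overlapping fruit. Passing end-to-end tests on these scenes therefore
demonstrates that the *algorithmic chain* behaves as specified under the
intended statistical structure — not that the detector reaches any
particular accuracy on real orchard images.

## Problem sizes and reproducibility

The package's own experiments use 100 training scenes and 50 held-out
evaluation scenes at 300×400 px — several hundred regions per role, enough
for stable stratified means while keeping a full run in the order of a
minute on one core. `scripts/acceptance.R --seed S --out f.json` reruns
the whole experiment from scratch, plus brute-force cross-checks of the
Otsu threshold (exhaustive 256-candidate search) and of GLCM construction
(double-loop pair enumeration), writing every quantity with the problem
size it was measured on. All randomness derives from the single seed.

## Known limitations

* The texture contrast between fruit and soil weakens for very small
  regions, where boundary pairs against the zero background dominate both
  classes; misclassified slivers do occur and are visible in the
  incomplete-stratum sensitivity.
* Label maps stored as 8-bit PNG cap at 255 regions per image.
* The classifier is strictly linear and two-class by design; enabling
  correlation as a third feature is supported but not beneficial on the
  generator's scenes.
* Trained coefficients depend on the training scenes; only the procedure,
  not any particular (ω*, b*), is reproducible across datasets.
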