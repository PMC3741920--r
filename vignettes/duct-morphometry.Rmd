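---
title: "Quantifying duct atypia: models, parameters and design choices"
author: "ductmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying duct atypia: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is graded from duct morphology: a
normal duct is a roughly convex lumen ringed by cuboidal epithelium with
nuclei aligned along the boundary; as carcinoma develops, the lumen grows
papillary projections and irregular contours, the epithelium becomes
columnar (long cytoplasm between nucleus and lumen) and nuclear polarity is
lost (the nucleus-to-lumen distance becomes erratic). `ductmorph`
quantifies exactly these changes in a single-duct H&E image crop. It
segments three objects — the lumen, the epithelial nuclei, and the
remaining (non-epithelial) nuclei — and computes per image twelve classical
morphometrics for each object plus six duct-atypia features.

## Segmentation

**Lumen.** The luminance channel is median filtered (radius 2 px) and
thresholded with Kapur's maximum-entropy criterion over the 256-bin
histogram; bright, lumen-like pixels become a binary map. A *direction
cumulative map* assigns every white pixel the sum over the four axis
directions of the square root of the white-run length in that direction;
the run excludes the pixel itself, so isolated pixels score zero and the
map peaks near the centres of wide bright areas while narrow corridors are
suppressed. The map is thresholded with Otsu's method on its nonzero
values, and the local maxima (one per plateau, at its centroid) seed a
region-growing step: seed clusters of similar intensity grow while a
pixel's intensity stays within `srg_tol = 0.15` of the evolving region
mean, regions that meet merge, and the lumen is the largest grown region
that does not hug the image border. The border rule reflects how the input
images are made — each crop contains one whole duct, so a region covering
the frame is background, not lumen; on a featureless image the frame is
returned with a warning.

An optional rolling-ball illumination correction (morphological opening of
the luminance with a disc, subtracted) is available via
`background_radius`, but defaults to off: background flattening is only
meaningful when the ball is larger than every structure of interest, and in
a single-duct crop the lumen itself is usually the largest structure in the
frame.

**Nuclei.** After median filtering, pixels are clustered in RGB by k-means
with `k = 3` (nuclei, stroma, lumen). Centres are seeded
deterministically at the extreme and middle luminance quantiles — tissue
classes differ in brightness, not in pixel mass, and anchoring one centre
on the darkest pixels keeps the sparse nuclear class from being absorbed
into the stroma. The darkest cluster is kept only if it is at least
`min_contrast = 0.08` luminance below the next cluster (hematoxylin is far
darker than eosin; without a genuinely dark mode the image is treated as
nucleus-free). Holes are filled, touching nuclei are split by a watershed
on the distance transform, and components under `min_nucleus_area = 10` px
are dropped.

**Epithelial split.** For every point of the traced lumen boundary the
nucleus with the nearest centroid is marked epithelial (ties resolved
toward the smallest nucleus index, making the result deterministic); the
rest are non-epithelial. No distance cap is applied — every boundary point
elects a nucleus — so the phantom generator keeps stromal nuclei farther
from the boundary than any epithelial nucleus can be.

## The atypia features

**Ideal boundary.** The atypia-free reference shape `B^I` is the convex
hull of the lumen boundary, rescaled about the hull centroid by
`s = sqrt(Area(R^O)/Area(R^C))` so its enclosed area equals the lumen
area, then resampled to uniform ~1 px arc-length spacing. The square root
is required for a linear scaling to reproduce the target area. Because the
construction is area-preserving, protrusions beyond `B^I` are always
balanced by an equal area of intrusions — a fact that shapes both the
feature behaviour and the phantom design below.

**Signature.** For each point of `B^I` a line is cast along the local
outward normal (tangent by central differences) and intersected with the
lumen boundary polygon; the nearest intersection `q` gives the amplitude
`A(t)`, positive when `q` lies outside the region enclosed by `B^I` and
negative inside. The abscissa `L(t)` is the cumulative arc length from the
start point (the topmost-then-leftmost vertex; all boundaries are stored
counter-clockwise from that vertex so signatures of identical shapes
align). Should the normal line miss the polygon entirely (a numerical
corner case), the nearest boundary point is used with a point-in-region
sign. Signature units are pixels; features convert to micrometres with the
image resolution.

* **RMSAA** is the root mean square of `A(t)` — the overall deviation from
  the ideal shape, reported in micrometres.
* **PIPs / TSAV.** Perceptually important points are found by recursive
  bisection in the `(L, A)` plane: within each interval the point with the
  largest vertical distance from the chord becomes a PIP when that distance
  exceeds `pip_T` (default 1 px), and recursion continues on both sides —
  so the procedure finds *all* critical points above the threshold rather
  than a fixed count. A pruning pass then repeatedly removes the interior
  PIP with the smallest turning angle while any angle is below `theta_min`
  (default 5°), discarding near-collinear points. TSAV sums the turning
  angles at the remaining interior PIPs (radians); it grows with both the
  amplitude and the frequency of boundary oscillation. Because angles are
  measured in the pixel-unit signature plane, `pip_T` and TSAV are
  resolution-dependent by design; all images of a study should share one
  resolution.
* **Atypia regions.** The symmetric difference between the lumen region
  and the ideal region is separated *by the ideal boundary* into
  protrusions and intrusions; each side is labelled into 4-connected
  components. Labelling the two sides separately is essential — a single
  labelling of the symmetric difference would merge protrusions and
  intrusions at the corner pixels where they meet. `AtypiaRatio` is total
  component area over lumen area (all components); `#AtypiaRegions` counts
  components larger than `atypia_threshold_um2` (default 300 µm²), i.e.
  the papillae.
* **Cytoplasm length.** Distance from each epithelial nucleus centroid to
  the lumen boundary polyline; the per-image feature is the mean, and its
  *population* standard deviation (divisor `m`, as the defining formula is
  written) quantifies loss of nuclear polarity.

## The phantom generator

`generateDuctPhantom()` renders a duct with known ground truth: a bright,
near-white lumen (RGB ≈ 245) on an eosin-like stroma (RGB ≈ 200/140/170)
with Gaussian texture (sd 0.035) — the texture matters, because an
untextured synthetic stroma produces a degenerate three-spike histogram on
which entropy thresholding is unstable in a way real H&E never is — plus
hematoxylin-dark elliptical nuclei. Epithelial nuclei are placed along the
boundary at an exact offset along the local outward normal (their long
axis radial: columnar), stromal nuclei are scattered at a clearance larger
than any epithelial distance so the nearest-nucleus rule cannot elect
them, and a minimum 3 px gap between nuclei keeps the watershed split
exact.

**Papillae with an analytic region count.** Papillae project *into* the
lumen and are rendered as inward elliptical bites (area `lobe_area_um2`,
depth 2.6 times the half-width). Area preservation forces an equal
balancing area on the other side of the ideal boundary; left alone it
would form large spurious components and break the expected count. The rim
is therefore crenellated — a square wave of period 24 px whose trough
depth is set in closed form from the area balance
(`delta_out = delta_in + k·A/(pi·r)`) — so every balancing sliver is a
crest or trough piece of analytic area `lambda/2 · delta`, far below the
300 µm² counting threshold, while every papilla core stays far above it.
The expected count is then exactly `n_lobes`, verified for `k = 0..5`.
Square-wave crenellation (rather than a sine) also survives median
filtering, which preserves step edges but attenuates short-wavelength
ripples.

**Grade templates.** `gradePhantomConfigs()` encodes the study conditions
of a three-class cohort: lumen radii reproducing mean lumen areas of about
3.8·10⁴, 6.8·10⁴ and 1.2·10⁵ µm², papilla counts 0 / 2 / 5, cytoplasm
offsets 6.2 / 12.9 / 15.9 µm with polarity jitter 2.1 / 5.75 / 8.47 µm,
and low-order boundary noise rising with grade — all taken from the
per-grade group means reported for real tissue, so effect sizes are
realistic rather than convenient. On top of the nominal values, each
rendered duct draws its own radius, papilla count and mean offset
(`lumen_radius_sd`, `n_lobes_sd`, `offset_between_sd`; normal draws,
radius truncated at two standard deviations, cell counts scaled with the
realized radius): the reported per-grade confidence intervals imply large
duct-to-duct spread, and without it the grades would be implausibly easy
to separate. Phantoms are rendered at 0.984 µm/px
(a 2× binning of the 0.492 µm/px slide resolution) to keep rasters
compact; all geometric parameters are specified in micrometres, so the
physical conditions do not depend on this choice.

What the phantoms deliberately do **not** emulate: staining variability
and chromatic noise, out-of-focus blur, cribriform (multi-lumen) ducts,
overlapping nuclei, mitotic figures, and solid Grade-3 sheets. Passing
phantom tests therefore demonstrates that the geometry pipeline measures
what it claims on images whose ground truth is known — not that the
segmentation is robust to every artefact of real slides.

## The evaluation protocol

Feature sets follow the published compositions: classical sets per object
(CNF, CLF, CEF, 12 each), the proposed lumen set PLF (RMSAA, TSAV,
AtypiaRatio, #AtypiaRegions) and epithelial set PEF (CytoplasmLength and
its SD), and their unions up to all 42 features (ATF). For each labelled
dataset the classifier is a soft-margin RBF SVM; each of 10 repetitions
draws a stratified 60/40 train/test split, standardizes features on the
training split (z-scores; the printed narrow gamma grid presumes
comparable scales), selects `(C*, gamma*)` from the printed grids
`C ∈ 10^(-1 .. 4)` and `gamma ∈ 2^(-5 .. 0)` (half-decade/half-octave
steps) by 10-fold cross-validated accuracy with ties resolved toward the
smallest `C` then the smallest `gamma` (the smoothest model), and scores
the held-out split. Reported numbers are means and SDs of the confusion
counts, the five percentage measures, and the trapezoid AUC; ROC curves
are vertically averaged on a common false-positive grid. True
with-replacement bootstrap resampling of the training split is available
(`resample = "bootstrap"`), with repeated splitting as the default
reading of "10 training and 10 testing sets". The two-class cases mirror
the published design: normal vs carcinoma (the carcinoma arm subsampled
to 80 balanced across grades) and grade 1 vs grade 2. Feature screening
uses per-feature one-way ANOVA (`alpha = 0.01`) with Fisher's LSD
post hoc on the three group pairs.

## Numerical choices and degenerate inputs

* Rasters are `[x, y]` matrices (EBImage convention); boundaries are
  1-based pixel-centre coordinates, counter-clockwise, starting at the
  topmost-then-leftmost vertex. Identical shapes yield identical point
  sequences, which makes every downstream feature deterministic.
* Perimeter is measured on the traced contour after a 5-point circular
  moving average: a raw 4-connected trace is a staircase whose length
  overestimates smooth perimeters by up to 4/π. Feret diameter is taken
  over pixel corners so a w×h rectangle measures its full diagonal.
  Solidity uses the filled convex-hull mask, guaranteeing values ≤ 1.
* Best-fit ellipse axes come from the second central moments with the
   1/12 px² pixel-footprint term; axes are 4·sqrt(eigenvalue).
* Skewness is the third standardized moment of the luminance inside the
  region (the intensity convention), 0 when no intensity is supplied.
* `arccos` arguments are clamped to [−1, 1]; duplicate PIPs raise an
  error rather than yielding NaN angles.
* Constant images make the entropy threshold undefined: an empty mask and
  a warning, and the pipeline row is flagged `lumen_not_found`.
* A zero denominator in a confusion measure yields `NA`, never 0.
* Every stochastic step (phantom rendering, cohort seeds, splits, folds)
  is driven by an explicit seed and restores the caller's RNG state.

## Problem sizes

The bundled checks run on: a 240-image cohort (80 per grade, images
roughly 300–560 px square), 50 papillary phantoms for count recovery,
20 convex phantoms for the zero-atypia limit, 1000 random 50-point
signatures against the brute-force PIP oracle, and 100 random star
polygons for area preservation — sizes chosen so the full suite completes
in minutes on one core while keeping every estimate comfortably away from
its decision boundary.

## Known limitations

* One duct per image; cribriform and multi-duct fields are out of scope.
* TSAV depends on the signature sampling density and `pip_T`; compare
  TSAV values only across images processed with one configuration.
* The epithelial split has no distance cap, so in tissue with sparse
  epithelium a remote nucleus can be elected; real deployments may want a
  cap at a few nuclear diameters.
* The SVM protocol reports split-resampling means; with 10 repetitions the
  SDs themselves are noisy, as the wide printed SDs of the original tables
  suggest.
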