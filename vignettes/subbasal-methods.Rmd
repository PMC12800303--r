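---
title: "Quantifying corneal subbasal nerves and dendritic cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corneal subbasal nerves and dendritic cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In vivo confocal microscopy (IVCM) of the cornea images the subbasal nerve
plexus — a dense, roughly parallel layer of nerve fibres just beneath the
epithelium — together with resident dendritic immune cells (DCs). Two
quantities are clinically useful:

* **CNFL density** (mm/mm²): total nerve fibre length per image area,
  averaged over a participant's images;
* **DC density** (cells/mm²), split into cells *with* visible dendritic
  processes and compact cells *without* them.

The reference ("manual") measurement traces nerves point by point (NeuronJ
`.ndf` polylines) and outlines cells as polygons (Labelme-style JSON). This
package implements the automated counterpart — residual U-Net segmentation
followed by rule-based measurement — plus the full agreement and
group-statistics harness, and a synthetic image generator that makes every
stage testable against analytically known ground truth.

The per-participant closed forms are deliberately trivial and exact:

* CNFL density = mean per-image nerve length (mm) / image area (mm²),
* per-class DC density = mean per-image count / image area,
* total DC density = with-dendrites density + without-dendrites density.

With the default field (400 × 400 µm at 384 × 384 px) the image area is
0.16 mm², so one cell per image corresponds to 6.25 cells/mm². These
identities anchor several tests.

## Geometry conventions

One coordinate convention is used everywhere: `x` = column, `y` = row,
origin at the top-left pixel centre, 0-based. Choices that the formats
themselves leave open are fixed so that pixel counts are testable:

* **Stroke rasterization** (nerve masks, default width 4 px): a pixel is
  foreground when its centre lies at signed perpendicular offset in
  `[-w/2, w/2)` from a segment, at an axial position within the segment.
  Polyline ends get butt caps; interior joints get round joins (a disk of
  radius `w/2`). The half-open band makes a width-4 horizontal line cover
  exactly 4 rows.
* **Polygon fill** (cell masks): even-odd rule on pixel centres, half-open
  so abutting polygons never double-cover. Cross-class overlap resolves by
  draw order, last drawn wins, which preserves the one-hot property of the
  3-channel mask (background / with dendrites / without dendrites).
* **NDF dialect**: a minimal NeuronJ-compatible subset — version line,
  preserved header lines, `// Tracing <name>` blocks with one coordinate
  per line alternating x and y. Integer-coordinate files round-trip
  bit-identically; real coordinates are accepted and rounded only at
  rasterization.

## Nerve length from a binary mask

The algorithmic estimator is topology-preserving Zhang–Suen thinning
followed by weighted link counting on the 1-px skeleton: orthogonal
8-neighbour links count 1 px, diagonal links √2 px, and length in mm is
the weighted sum times the pixel pitch. Two details matter:

* **Chord exclusion.** After thinning, an L-corner can carry both its two
  orthogonal links and the diagonal "chord" between their endpoints.
  Counting all three would measure the corner twice, so a diagonal link is
  skipped when its two pixels share a foreground orthogonal neighbour.
  Pure straight and pure diagonal chains are unaffected (they reproduce
  their closed-form lengths exactly).
* **Spur pruning** (default 2 px, half the default stroke width): terminal
  branches this short are rasterization artefacts of the stroke edges, not
  nerve structure. Pruning is configurable and can be disabled.

The estimator's error budget on rasterized curves: thinning retracts each
butt-capped stroke end by about half the stroke width (a fixed ≈2 px per
end), and the √2 weighting overestimates slightly for tangents between 0°
and 45°. For the generator's near-vertical, gently curved fibres the two
effects largely cancel; the per-curve 5% recovery guarantee asserted in the
tests therefore holds for tangents within ≈15° of vertical and arc lengths
of at least 100 px, and the aggregate error over random default-parameter
curves is asserted at the same 5% level. Very short fragments are dominated
by the fixed end cost — a genuine property of any skeleton-based length
measure, documented rather than patched.

An alternative per-image proxy (foreground pixel count divided by nominal
stroke width) is available behind a flag; the skeleton path length is the
default.

## The regression estimator and estimator selection

Skeleton length is sensitive to segmentation breaks: every false gap costs
about a stroke width of length. The regression alternative reuses the
segmentation encoder (residual blocks + max-pooling), global-average-pools
the deepest feature map, and maps it through a dense layer with a softplus
output to a non-negative length in mm, trained with squared error against
ground-truth lengths. `select_estimator()` compares both methods by MAPE
(ties: MAE, then the simpler algorithmic method) and the pipeline carries
the winner forward. Which method wins is scale-dependent: with abundant
training data the regressor can learn to offset systematic segmentation
errors, while at the desk scales used in the test suite the algorithmic
method is usually selected.

## Segmentation models

Both models are residual U-Nets: residual blocks (3×3 conv – ReLU – 3×3
conv plus a projected shortcut, ReLU after the sum) at each resolution
level, 2×2 max-pooling down, nearest-neighbour upsampling with skip
concatenation up, and a 1×1 head — sigmoid for the binary nerve mask,
3-way softmax for the one-hot DC mask. The published architecture family
is parameterized here by `depth` and `base_channels` (reference default
depth 5 / base 16; the test suite uses depth 3 / base 8). The default loss
is compound Dice + cross-entropy; Dice alone, BCE and CE are selectable.
Binarization uses threshold 0.5; the 3-class head takes the per-pixel
argmax.

Because no deep-learning framework is assumed, the package ships its own
CPU training core: im2col+GEMM convolutions (RcppArmadillo) with
hand-written backpropagation, verified against central-difference numerical
gradients in the test suite, and Adam. Training is deterministic given the
config seed (single-threaded, no augmentation — none is used by default).

Cross-validation is subject-stratified: `make_folds()` assigns every
subject to exactly one of k folds (sizes differing by at most one subject),
deterministically given the seed and independent of image order, so no
image of a held-out subject can leak into training.

## The synthetic generator

`generate_sample()` draws bright, predominantly vertical nerve fibres
(base deviation from vertical N(0, 8°), sinusoidal tangent wiggle of
3–10° amplitude and 150–400 px wavelength, stroke widths 3–5 px — matching
the appearance criteria used when selecting clinical images), plus cell
bodies as jittered ellipses with semi-axes 3.5–5.5 px (≈7–11 µm diameter,
a realistic DC body size) where the with-dendrites class carries 2–4 thin
radiating processes. The background is a smooth random field plus
multiplicative speckle and additive Gaussian noise, lightly blurred. The
noise model is intentionally generic: it exists to make segmentation
non-trivial, not to be photorealistic. Ground truth is exact by
construction: arc length from the generating polyline, counts and classes
from the generated polygons.

`generate_cohort()` adds two-group subject-level structure with defaults
matching the study population this package models: subject CNFL density
N(17.3, 3.8²) vs N(19.4, 4.0²) mm/mm², DC densities 11.6 ± 14.1 /
59.8 ± 53.4 vs 6.6 ± 6.0 / 36.0 ± 42.0 cells/mm² (all truncated at zero —
densities are non-negative), two eyes per subject, per-image nerve length
equal to the subject target times truncated-normal noise (CV 10%,
generated to the exact per-image target), and per-image cell counts
Poisson around the subject's latent density times area.

**What passing tests do and do not show.** The generator reproduces the
geometry and first-order appearance statistics of the clinical images, so
passing tests demonstrate the pipeline's correctness and its recovery
behaviour under known ground truth. They do not certify clinical
performance: real IVCM adds imaging artefacts (motion, oblique sections,
pressure lines), anatomy the generator omits (branching nerves, beading,
nerve-adjacent cells), and annotation ambiguity.

### Desk-scale choices

The test suite and acceptance script run everything at desk scale, chosen
once: 96 × 96 px crops at the full pixel pitch, 5 subjects per group, 2
images per eye, depth-3/base-8 networks trained for 30 (nerves) or 45
(cells) epochs, and a depth-3/base-8 regression encoder. Nerve length
targets scale with crop area, since fibres are extended structures. Cell
counts do **not** scale with crop area: cells are discrete objects, and a
count-scaled 96-px crop would contain a fraction of a cell per image,
leaving nothing to count or learn. The cohort generator therefore supports
`dc_count_area_mm2 = 0.16`, which keeps the study's per-image count
distribution on the smaller crop; densities computed from those counts are
referenced back to 0.16 mm². The trade-off — cells are more crowded per
unit area than in the full field — is accepted and documented.

The pipeline reports two cell-count errors: the per-image **total** count
MAE (the quantity whose ±1-cell magnitude is argued to be clinically
negligible) and the per-class MAE, which additionally absorbs
with/without-dendrites confusion — by far the harder discrimination, and
the one the study's own class-wise errors show to be weakest.

## Agreement and group statistics

* Bland–Altman: bias = mean(auto − manual), sample SD (n−1), limits
  bias ± 1.96·SD (the large-n normal multiplier, not a t quantile).
* ICC: two-way, absolute agreement. The single-rater form ICC(A,1) is the
  default (reliability of one measurement); the average-measures form
  ICC(A,k) is selectable, since "average ICC" in reports can mean either.
  Confidence intervals use the standard F-based construction with
  Satterthwaite denominator degrees of freedom.
* Pearson r with a Fisher-z interval, `tanh(atanh(r) ± z/√(n−3))`.
* MAPE excludes zero-truth pairs with a warning (the measurands are
  positive); MAE is plain.
* Empty-vs-empty masks define Dice/recall/precision as 1 — perfect
  agreement on absence.
* Levene's test is one-way ANOVA on |x − centre|; centre = mean is the
  classic test (the default), centre = median the Brown–Forsythe variant.
* The group comparison is the pooled-variance t-test (df = n1+n2−2) with
  pooled-SD Cohen's d, and Benjamini–Hochberg adjustment across measures.
  A summary-statistic input mode allows checking published group tables
  directly. Repeated-measures mixed models are out of scope by design:
  per-participant averaging already collapses the within-subject
  structure, so the supported path runs the t-test on per-participant
  densities.

## Degenerate inputs and numerical edges

* Empty tracing → all-zero mask; empty mask → zero length (not errors).
* Empty per-participant input → error (participants without usable images
  are excluded, not imputed as zero).
* ICC with zero total variance is 1 when the two columns are identical,
  an error otherwise; Pearson r with a zero-variance column is an error.
* Cell components touching the image border are counted; touching cells of
  the same class merge into one component — a known limitation of
  count-by-components shared with the manual protocol in crowded images.
* The minimum component area (default 10 px) keeps single-pixel noise out
  of counts and sits safely below the smallest generated cell body
  (≈24 px).
* The image area 0.16 mm² is exact in real arithmetic; in double
  precision 400/384 carries ≈1e-16 of rounding, so "exact" assertions use
  1e-12 tolerances.

## Known limitations

* The training core is CPU-only and desk-scale by design; it demonstrates
  the pipeline, not clinical-scale performance.
* The with/without-dendrites distinction is learned only from the presence
  of thin processes; real morphology is richer.
* Nerve branching is not modelled, so the generator cannot probe
  branch-point handling in the length estimator.
* The regression estimator's advantage over the algorithmic one emerges
  with training data volumes beyond what the test suite uses.
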