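---
title: "Methods: leaf-state-aware rosette phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf-state-aware rosette phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettephen)
```

## The measurement problem

A top-view image of a single Arabidopsis rosette, together with a
per-pixel class mask, is the raw material of image-based phenotyping.
The mask assigns each pixel to background or to one of up to three leaf
states: green healthy tissue (`class_norm`), anthocyanin-rich tissue
(`class_antho`, the purple pigmentation of stressed plants), and
senescent or dead tissue (`class_senesc`). This package turns each
image/mask pair into one row of a trait table and provides the
surrounding machinery — batch processing, mask evaluation, a classical
color-segmentation comparator, and a synthetic scene generator that makes
every step testable without external data.

Three mask vocabularies are supported. Scheme C carries all three leaf
states; scheme B merges green and anthocyanin-rich into one non-senescent
class; scheme A is a plain plant/background split that deliberately
treats senescent tissue as background. Labels are consecutive integers
from 0 (`background`) in listed class order, a fixed repository
convention so that CSV columns mean the same thing in every run. The
compound `plant_region` — the union of green and anthocyanin-rich pixels,
i.e. living tissue — gets its own trait block; under schemes A and B it
coincides with `class_norm`, and the columns are still emitted so the
schema depends only on the scheme, not on the image.

Coarsening (`coarsen_mask()`) maps C→B by folding `class_antho` into
`class_norm`, and any scheme →A by additionally sending `class_senesc`
to background. Both rules move every pixel to exactly one target label,
so living-tissue pixel counts are conserved exactly; C→A equals C→B→A
pixelwise, which the test suite asserts as a property.

## Morphometric traits

All pixels of a class are treated as **one region even when
disconnected**: the phenotyping unit is one plant per image, and
whole-rosette descriptors such as the convex hull must span all leaves of
the class. Eleven shape traits are computed per class:

* `area` — pixel count; `filled_area` — pixel count after filling
  enclosed holes; `convex_area` — pixel centers inside or on the convex
  hull of the class's pixel centers;
* `equivalent_diameter = sqrt(4·area/π)`, the diameter of the circle with
  the same pixel count;
* ellipse axes from the normalized second central moments of the pixel
  coordinates: with eigenvalues λ₁ ≥ λ₂ of the covariance matrix of pixel
  centers, `major = 4√λ₁`, `minor = 4√λ₂`, and
  `eccentricity = sqrt(1 − λ₂/λ₁)`;
* `perimeter` — summed step lengths along the traced outer contour of
  each 8-connected component (1 per straight step, √2 per diagonal);
* `extent = area / bounding-box area`, `solidity = area / convex_area`,
  `aspect_ratio = major / minor`.

Numerical conventions worth stating explicitly:

* **No pixel-extent correction** is added to the moments, so a single
  pixel has zero-length axes and eccentricity 0 rather than the
  1/12-inflated axes some implementations report. This keeps degenerate
  regions unambiguous.
* The **convex hull** is taken over pixel centers and `convex_area`
  counts pixel centers inside or on it (half-plane test with a 10⁻⁹
  slack). Collinear regions, where the hull degenerates, fall back to the
  pixel count — which is exactly the set of centers on the segment.
* **Hole filling** floods the background from the image border with
  4-connectivity; foreground connectivity is 8. Using the complementary
  pair avoids the classical paradox of a diagonal line enclosing a
  "hole" under matching connectivities.
* An **absent class** yields `area = 0` and missing values for every
  other trait, distinguishing "no such tissue on this plant" from
  degenerate geometry; missing values are written as empty CSV fields.

Invariants covered by property tests: translation invariance; 90°
rotation preserving area, convex area, solidity and eccentricity;
`area ≤ filled_area ≤ convex_area`; exact agreement of area/extent/bbox
with exhaustive counting and of `convex_area` with a brute-force
hull-membership oracle on random blobs; solidity 1 for rasterized
rectangles and disks (any pixel center in the hull of a convex rasterized
set is itself in the set).

## Color traits

Channel means are computed over exactly the class pixels of the original
RGB image, and the five chroma indices are computed **from the means**,
not as per-pixel indices averaged afterwards — the order of operations
matters because the indices are ratios. Zero denominators (e.g. a region
with no green signal at all) produce missing values rather than
infinities, keeping the results table analysis-safe. The algebraic
identity `chroma_ratio × chroma_base = 2` holds wherever both indices are
defined and is verified to 10⁻⁹ on 10,000 random triples; it is a useful
internal consistency check precisely because the two indices are computed
through independent code paths of the same formula block.

## Baseline segmentation and multi-scale inference

The classical comparator converts the image to CIELAB (sRGB, D65) and
labels a pixel as plant when `a* ≤ a_max` and `L* ≥ l_min`. Defaults
`a_max = −8`, `l_min = 15` give a reasonable green-versus-soil separation
on the synthetic fixtures and are exposed as arguments and CLI flags; the
green axis threshold is the load-bearing one, the lightness floor merely
rejects near-black shadow. The raw mask is post-processed by keeping the
largest 8-connected component and filling holes, the usual cleanup of
color pipelines. This baseline is a faithful stand-in for classical
color-based segmentation in general, not a reimplementation of any
specific commercial recipe; its purpose here is the failure-mode
regression: on synthetic all-green rosettes over soil it reaches
plant-class IoU ≈ 0.99, and on the same geometry recolored
anthocyanin-purple it collapses to ≈ 0 — purple tissue sits on the
positive a* side of the threshold by construction.

`multiscale_predict()` wraps any pixel classifier that returns per-class
score maps: the image is resized by each factor (bilinear; default set
0.5–1.75 in steps of 0.25, a conventional choice for this inference
family), classified, scores are resized back to native resolution,
averaged, renormalized per pixel (bilinear resampling preserves
nonnegativity but not exact unit sums), and argmaxed with ties broken
toward the lower label. Label masks themselves are only ever resized
nearest-neighbor so the vocabulary is preserved. No neural network is
bundled; the classifier interface is the extension point for externally
trained models, and the Lab threshold doubles as a one-hot demonstration
classifier.

## Evaluation

Segmentation accuracy is the mean intersection-over-union: per class,
`TP/(TP+FP+FN)` on pixel counts **pooled over all images** (the
convention of the common segmentation evaluation frameworks; the
alternative, averaging per-image IoUs, weights small plants up).
Background counts as a class; classes absent from both prediction and
truth are excluded from the mean to avoid 0/0. Pooling is implemented as
an explicit confusion accumulator so that batch order is provably
irrelevant, and the suite checks symmetry, additivity, agreement with a
set-theoretic oracle, and that label noise never improves a perfect
score.

Agreement between two per-image area series (e.g. the same plants
measured under schemes B and C) is the R² of an ordinary least-squares
fit on untransformed pixel areas, with intercept. In the exact limit —
areas from a C mask against the same mask coarsened to B — conservation
makes the relation the identity and R² is exactly 1, which the acceptance
checks exercise over 50 synthetic scenes.

## The synthetic scene generator

The generator emulates the geometry of the data this pipeline targets: a
single centered rosette of `leaf_count` elliptical leaves placed radially
(angle `2πl/n` plus Gaussian jitter, SD 0.12 rad), drawn back-to-front so
the rendered mask matches visible pixels exactly. Defaults are one
256×256 scene with 10 leaves of mean length 70 px and width 26 px
(SD 8 px) — a mid-size rosette occupying roughly a fifth of the frame, as
is typical for pot-level crops of phenotyping platforms. Each leaf draws
its state from `(p_norm, p_antho, p_senesc)` and its color from the
state's mean ± spread (per leaf, plus finer per-pixel grain at one fifth
of the spread): green (45,110,40), purple (95,40,85), brown-yellow
(150,120,60), spread 15 — plausible separations chosen as fixture
conventions, not measurements. Backgrounds: solid gray, a blue plastic
mesh (periodic blue lines over dark gray, the classic growth-facility
background), soil (brown Gaussian noise), and soil with sparse green
algae speckle — the canonical false-positive source for color-based
segmentation, which the largest-component cleanup and multi-scale
averaging are meant to suppress. Every scene's randomness comes from one
stream derived from `(seed, scene index)`, so data sets are reproducible
independently of generation order, and generation restores the caller's
RNG state.

`generate_time_series()` emulates an aging experiment: leaf count grows
linearly from 60% to 140% of the template across the age range, and the
state mix follows a user mapping such as `senescence_ramp()`, which
raises the senescent probability linearly (default 0.02 → 0.6 across the
range, with anthocyanin at a quarter of the non-senescent remainder).
With per-leaf state sampling and ~6–14 leaves per rosette, the
*per-scene* senescent fraction carries binomial leaf-level noise of
SD ≈ √(p(1−p)/n) ≈ 0.15, so trend recovery is assessed on the **per-age
mean** share across replicates — the same aggregation a
leaf-states-over-time figure plots — where the Spearman correlation with
age is ≈ 1; the raw per-scene correlation (≈ 0.8 under defaults) is also
reported by the acceptance script and asserted above 0.6 in the unit
tests.

What the generator does **not** emulate: perspective and lens distortion,
leaf overlap in 3D (occlusion is purely painter's-algorithm), petioles
and serrated leaf margins, specular highlights, within-leaf color
gradients, and soft class boundaries — real senescence is gradual within
a leaf, whereas generated leaves are uniformly one state. Passing tests
on synthetic scenes therefore validate the *measurement* machinery
(counting, geometry, color arithmetic, evaluation, determinism), not the
segmentation difficulty of real images.

## Pipeline determinism and problem sizes

The scatter step orders inputs lexicographically and cuts them into
`⌈N/batch_size⌉` consecutive batches (default size 10, a laptop-friendly
unit); batches share no mutable state and the gather step restores input
order and rejects duplicate identifiers, so the same inputs and
configuration yield a byte-identical `results.csv` regardless of batch
size. Images are paired to masks by file stem and a missing mask is an
error, not a silent drop; per-image failures are collected and reported,
with `strict = TRUE` (default) turning any failure into a nonzero exit
after the run completes.

The shipped checks use problem sizes chosen to exercise each property
convincingly while keeping the default suite fast on a single CPU:
10,000 random triples for the chroma identity, 100 random 16×16 mask
pairs against the IoU oracle, 50 shapes for the morphometric oracle
suite, 50 default-size scenes for coarsening conservation, a 10-age ×
20-replicate time series for trend recovery, 5 + 5 scenes at 160×160 for
the baseline regression, and 100 mixed-state 256×256 scenes for the
end-to-end determinism check.

## Known limitations

* Traits are reported in pixels; physical calibration (mm/px) is the
  caller's responsibility.
* No instance segmentation: leaves are never separated, so leaf counts
  and per-leaf traits are out of scope.
* The color indices are uncalibrated ratios of raw channel intensities;
  they order plants within one imaging setup but are not comparable
  across cameras or illumination without external normalization.
* The Lab-threshold baseline is intentionally simple; it is a comparator
  and a fallback, not a recommended segmenter for stressed plants — its
  failure on anthocyanin-rich tissue is the package's own regression
  fixture.
* Perimeter uses the weighted contour-step approximation, which
  overestimates the length of smooth curves by up to a few percent; it is
  consistent across images, which is what comparative phenotyping needs.
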