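---
title: "Measuring tip-marked filopodia from label masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tip-marked filopodia from label masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filomorph)
```

## The measurement problem

Filopodia are thin, actin-bundled membrane protrusions, typically 1-10 um
long, that cells use to probe their surroundings. They are visualised either
with an actin label (phalloidin) that shows the whole shaft, or with a
tip-marker protein -- Myo10 in mammalian cells, DdMyo7 in *Dictyostelium*,
VASP or formins -- that concentrates in a bright punctum at each filopodium
tip while keeping a visible cytosolic pool. Upstream segmentation (typically
a U-net, but any classifier will do) turns such images into semantic label
masks; `filomorph` is the measurement stage that turns masks plus raw
images into per-cell and per-filopodium numbers.

Two acquisition settings are supported:

* **tip mode** (`run_filotips()`): a single channel, mask classes
  background / cell body / filopodia tip. The cytosolic pool outlines the
  body; filopodia are tip puncta, and their length is the straight-line
  distance from the punctum to the cell edge.
* **skeleton mode** (`run_filoskeleton()`): an actin mask (background /
  body / stalk) plus a binary tip mask from the tip-marker channel. Shaft
  length is measured by tracing along the stalk, which is what you want for
  long, curled filopodia whose straight-line distance underestimates the
  true shaft.

## From mask to objects

Objects are 8-connected components of one mask class. 8-connectivity is
deliberate: tips and stalks are routinely one pixel wide and would fragment
under 4-connectivity. Components smaller than `min_body_area_px` (default
50) or `min_tip_area_px` (default 2) are treated as debris. Each region
carries its ordered outer boundary, traced with the Moore neighbourhood so
the perimeter is the arc length of a closed polyline through pixel centres
(axial step 1, diagonal step sqrt(2)).

Per cell, the morphometrics are:

* area = pixel count x (pixel size)^2;
* perimeter = boundary polyline arc length x pixel size;
* aspect ratio = short / long side of the minimum-area rotated bounding
  rectangle (rotating calipers over the convex hull of the boundary, each
  side extended by one pixel footprint so an n x m pixel block scores
  exactly min/max). 1 means square-ish, small values mean elongated;
* circularity = 4 pi A / P^2 in pixel units; 1 for a disc up to
  rasterisation (a single-pixel region has zero polyline perimeter, so
  circularity is reported missing);
* centroid in 0-based pixel coordinates, x = column, y = row, row 0 on top.

## Cortex, separator, interior

Tip-marker proteins are often enriched at the cell cortex, and the
cortex/body intensity ratio is the headline per-cell statistic: a value of
1.2 means 1.2-fold enrichment at the edge. To measure it reproducibly the
body is partitioned by depth `d`, the Euclidean distance to the nearest
non-body pixel (so boundary pixels have depth 1):

* **cortex**: `d <= 6` px -- the thin inner band overlapping the contour;
* **separator**: the next 15 px of depth -- a neutral gray buffer so cortex
  and body signal cannot contaminate each other;
* **interior**: everything deeper; `body_mean` is taken here.

The band widths are configuration parameters (`cortex_band_px`,
`separator_band_px`) because their published values carry a tilde -- the
original tool's exact widths may differ by a pixel. Depth is computed with a
Euclidean distance transform rather than by drawing thickened contour
lines: the result is deterministic, isotropic and independent of contour
orientation. Distance is taken to the background rather than to
boundary-pixel centres: discrete edge centres sit about half a pixel inside
the true contour, and measuring from them makes a nominal 6 px band about
10% too thick against the ideal annulus.

Cells too small to have an interior degenerate: the separator is dropped
first and the interior becomes everything below the cortex -- the cortex is
never sacrificed, because the enrichment ratio is the measurement the band
exists for. A `degenerate` flag is carried in the output. If even that
leaves no interior (bodies a dozen pixels across), `body_mean` and the
ratios are reported missing rather than computed from zero pixels.

The **leading edge** is the brightest cortex pixel plus its 49 nearest
cortex pixels (fewer if the cortex is smaller), capturing asymmetric
cortical enrichment in migrating cells. Intensity ties and distance ties
are broken by raster-scan order so the patch is deterministic.

All intensity statistics are computed on the raw image: the reader never
rescales, normalises or background-subtracts, so every exported ratio is a
ratio of raw camera values.

## Tip assignment and length (tip mode)

Each tip punctum is represented by its real-valued centroid (sub-pixel
stable, unlike a nearest-pixel representative). Euclidean distances from the
centroid to every boundary pixel of every cell are computed; the tip joins
the cell achieving the minimum, and that distance, scaled by the pixel size
(default 0.1099 um), is the filopodium length. A tip whose nearest cell
outline is farther than `max_tip_distance_um` (default 10 um) is an
**artifact**: it is excluded from all counts but still exported with a
reason, because a measurement library should be auditable rather than
silently drop records. Exact ties go to the lowest cell id and are flagged.

Per cell, the count of assigned tips and the perimeter-normalised density
`filopodia_per_10um = count / perimeter_um * 10` are reported; the density
is the more comparable statistic when cell sizes vary. `total_signal` sums
the raw image over the whole body region (all three bands) plus all
assigned tip pixels, so no pixel is dropped from totals.

## Shaft tracing (skeleton mode)

A tip focus within `tip_stalk_max_dist_px` (3 px) of a stalk is a
filopodium; the nearest stalk wins. The shaft walk starts at the stalk pixel
nearest the tip centroid and repeatedly moves to the stalk pixel within
`trace_step_px` (5 px) of the current waypoint that most reduces the
Euclidean distance to the nearest cell boundary. The published description
gives the intent ("move toward the nearest cortex along the stalk") but not
the rule; greedy descent with a strict-decrease requirement is the
documented choice here because it is deterministic and cannot oscillate.
Steps accumulate Euclidean length. When the walk comes within
`disembodied_min_dist_px` (5 px) of a body it terminates **attached**, the
remaining straight-line gap is added (otherwise lengths would systematically
undershoot by up to one step), and the filopodium belongs to the cell owning
the nearest boundary pixel. If no descending move exists and the whole
stalk keeps at least 5 px from every body, the fragment is **disembodied**:
reported, drawn with a blue tip in the annotation, excluded from counts. A
walk that stalls although the stalk does reach a body, or exceeds
`max_trace_steps` (2000), is **trace_failed** -- reported, never silently
truncated.

Crossing shafts are a known failure mode: where two stalks overlap they
form one connected component and the walk may continue down the wrong
shaft. Counts per cell remain valid; only the shaft length of the crossing
event is unreliable. The synthetic generator can produce flagged crossing
pairs on request precisely so length validation can exclude them.

## Segmentation metrics

For validating an upstream segmentation against ground truth the package
provides per-class IoU (intersection over union), pixel F1 (Dice; related
by F1 = 2 IoU / (1 + IoU)), and panoptic quality. Because the masks are
semantic, PQ instances are taken to be 8-connected components; a
predicted/true instance pair matches when its IoU exceeds 0.5 (the standard
threshold, which makes matching unique; it is exposed as a parameter), and
PQ = sum of matched IoU / (TP + FP/2 + FN/2). An absent class yields a
missing IoU rather than 0 so it cannot poison macro averages. The Pearson
harness (`pearson_validate()`) reports r, the two-sided p from the t
transform on n-2 degrees of freedom, and n; it never thresholds p itself.

## The synthetic generator, and what it does not emulate

`generate_tip_scene()` / `generate_skeleton_scene()` draw scenes with exact
ground truth: disc bodies (radius 18-28 px at the default 0.1099 um/px,
i.e. 2-3 um -- amoeboid scale), 3-8 protrusions per cell of 12-32 px,
3 px wide stalks (straight, L-shaped or constant-curvature arcs in skeleton
mode), 2 px tip puncta, intensity levels background 5 / body 100 / cortex
120 / tip 300 (a.u.), and optional additive Gaussian noise truncated at
zero. Cells are placed with boundary gaps of at least twice the maximum
protrusion length, the synthetic analogue of the low plating density that
every filopodia workflow requires, which guarantees unambiguous tip
assignment. Everything is deterministic per `(params, seed)`.

The generator intentionally shares the band-depth definition with the
engine, which is why noiseless cortex/body recovery is exact to 1e-6 -- that
round trip validates the bookkeeping, not the optics. What the generator
does **not** emulate: point-spread blur, Poisson shot noise (the additive
Gaussian slot is a deliberate simplification sufficient to stress
mean-based ratios), out-of-focus light, touching cells, or segmentation
errors other than the dropout of `perturb_mask()`. Passing recovery tests
therefore demonstrates correctness of the measurement engine downstream of
segmentation, not robustness of any particular segmentation model.

## Numerical choices and problem sizes

Distances and depths are double precision; comparisons that gate
assignment or tracing use 1e-9 slack so floating noise cannot flip a
decision. Tie-breaks (equidistant cells, equal intensities) always resolve
by raster-scan order or lowest id, and are flagged where scientifically
meaningful. The validation suite runs 50 noiseless tip scenes (2-5 cells
each) for count recovery, 20 scenes against an exhaustive assignment
oracle, 200 small scenes for partition exactness, and curved-stalk scenes
with 30-60 px protrusions for shaft-length checks against an igraph
shortest-path geodesic -- sizes chosen so the whole suite exercises every
rule at desk scale. Shorter stalks than ~25 px are not used for length
validation: at that scale rasterisation (up to 8% metric inflation of the
8-connected geodesic itself) dominates what is being measured.

## Limitations

* Touching cells are not split; plate sparsely or split upstream.
* Tip-mode lengths are straight-line by definition and underestimate curled
  filopodia; use skeleton mode for those.
* Crossing shafts yield unreliable individual lengths (flagged, counts
  unaffected).
* Sub-pixel boundary refinement is out of scope; all geometry is
  pixel-grid based.
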