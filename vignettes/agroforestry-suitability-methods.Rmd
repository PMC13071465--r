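---
title: "Methods: FAO-style agroforestry suitability and LULC change on raster grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FAO-style agroforestry suitability and LULC change on raster grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrosuit)
```

## The problem and the model

Mid-hill valley systems lose farmland in two directions at once: toward
built-up land along transport corridors where population concentrates,
and toward forest on remote terraces abandoned by out-migrating
households. This package implements the standard land-evaluation answer
to "which remaining farmland suits agroforestry?" — a multi-criteria
rank-and-weight overlay in the FAO suitability vocabulary — together
with the change-accounting toolkit needed to quantify where farmland
went.

Every layer lives on one shared planar grid (square cells, metres,
row 1 northernmost). Real-CRS reprojection is deliberately out of
scope: the computation is grid-local, and synthetic test scenes need no
geodesy. Rasters are read and written as ESRI ASCII grids, a
plain-text single-band format carrying origin, cell size and a nodata
sentinel; values are written at 17 significant digits so round trips
are exact.

### Criterion layers

* **NDVI** `(NIR − Red)/(NIR + Red)`; cells with zero band sum become
  nodata.
* **Tasseled-cap wetness**: a linear combination of six reflectance
  bands. The published OLI wetness coefficients are the default but the
  vector is configurable, because the rank thresholds in use
  (> 0 wet, below −0.2 dry) are conventions of the tasseled-cap space
  rather than of one sensor. Reflectance is assumed already scaled to
  [0, 1]; DN calibration is out of scope.
* **Slope** by Horn's 8-neighbour 3×3 kernel in degrees, the operator
  desktop GIS slope tools use; edges are handled by edge replication,
  which leaves a constant ramp's slope exact everywhere.
* **IDW surfaces** for soil pH, organic carbon, N, P, K and
  precipitation: weights `d^(−p)` over the `k` nearest samples, with
  `p = 2`, `k = 12`, and an exact-hit snap within 1 µm. Weights are
  normalized before combining, making the output a convex combination
  of sample values (bounded by their range) and a single-sample surface
  exactly constant. Kriging was not considered in scope; IDW is what
  the soil-survey workflow this mirrors actually uses.

### Ranking and overlay

Each criterion carries explicit breakpoint intervals mapping raw values
to ranks 3/2/1 (high/moderate/marginal). Two numerical conventions
matter:

* **Boundary resolution.** Printed tables like "> 560 / 560–280 / < 280"
  leave boundary membership ambiguous; here a shared boundary always
  belongs to the *lower-suitability* side (560 ranks 2), applied
  uniformly so the intervals tile the support without overlap. A value
  covered by no interval is an error, never a silent NA — break tables
  must be total.
* **pH gap fill.** The printed pH table leaves (5.5, 5.6) and (8.4, ∞)
  unassigned; nearest-interval continuity assigns the small gap to
  rank 2 and the alkaline tail to rank 1. Both extensions are recorded
  in the scheme object and echoed into the run provenance.

The three nutrient ranks are averaged with equal weights and
re-classified by equal thirds of [1, 3] (mean ≥ 7/3 high, ≥ 5/3
medium): the source tables give the nutrient-status layer only verbal
levels, so the thirds-on-mean rule is a documented stand-in chosen for
consistency with the composite classification below.

The composite score is `Σ w_i · rank_i` with weights stored as decimals
renormalized to sum exactly 1 (the printed 25 + 12.5·4 + 8.33·3 =
99.99% cannot). Scores are rounded at 1e−12 to scrub accumulation
dust, so unanimous ranks score exactly their rank and classification
boundaries behave deterministically. Classification uses equal thirds
of [1, 3] — S1 at score ≥ 7/3, S2 at ≥ 5/3, S3 below — as the
symmetric default for a score-to-class rule the source workflow leaves
unstated; the breaks are a scheme field so other rules can be tested.
S3 is fully supported even though typical outputs contain only S1/S2.

Classes are kept only on the agricultural LULC class; rock/river/
water/ice surfaces become "not suitable" (code 0); everything else is
nodata. Zone summaries report per-ward areas (hectares internally;
km² is presentation only), each class's share of the zone's suitable
land, and each zone's share of the municipality-wide class total, at
full precision — presentation rounding is half-up (`round_half_up()`),
matching how such tables are conventionally printed.

### Change accounting

Transitions between two dated maps are cross-tabulated over cells valid
at both dates; row/column sums therefore reproduce the per-date class
areas exactly (a tested invariant). The rural–urban gradient uses
Euclidean distance from cell centres to the nearest road segment,
banded at 500 m into 10 bands by default; the urban/rural split is the
same operation with a configurable cutoff, since the source workflow
names the highway as reference but no distance. Ward zones enter as a
label raster — rasterizing real boundary polygons is out of scope.

### Association and assessment statistics

Kendall's tau-b is used for the ward-level association of population
change with conversion areas because ward counts tie frequently; the
variant is recorded in the output. p-values use the tie-adjusted normal
approximation, with an exact permutation null below `exact_max = 8`
observations. The exact path enumerates all n! orderings, whose cost
and memory grow factorially; 8 keeps it instant while still serving as
the oracle for the enumeration tests (typical ward-level n of 20–33 is
comfortably asymptotic). Fully tied inputs return an undefined flag
rather than an error, since a ward table can legitimately degenerate.

Cohen's kappa follows the marginal-expectation formula; the degenerate
`p_e = 1` case reports 1 for a perfect matrix and undefined otherwise.
Landis–Koch labels use the standard bins (0.61–0.80 substantial,
0.81–1.00 almost perfect); nonstandard labels sometimes seen in print
("perfect" for 0.81) are deliberately not reproduced. Validation
points are assigned to cells by the half-open convention
(`x ∈ [left, right)`, `y ∈ (bottom, top]`) so boundary points resolve
deterministically; points on nodata cells are counted and reported,
never silently dropped.

## What the synthetic generator emulates

`generate_scene()` builds, from one integer seed, a scene with the
statistical structure the analysis assumes:

* a valley-to-hill DEM (default 450–1200 m over a 3.6 km scene — the
  real mid-hill relief spans more metres over far more kilometres, so
  the range is compressed to keep hillslopes realistic at this extent);
* a highway along the valley floor, and 20 Voronoi wards;
* six-class LULC (forest, agriculture, urban, barren/river, water,
  swamp) for 1990/2000/2010/2021: terraced farmland fills the valley
  and climbs past the 800 m elevation breakpoint, so elevation and
  slope ranks genuinely mix on farmland; per decade, agricultural cells
  urbanize with probability decaying with road distance and rising with
  ward population growth, and revert to forest with the complementary
  gradient;
* ward populations whose growth multipliers increase with road
  proximity and *decline* in remote wards — the out-migration/
  abandonment mechanism that makes agriculture-to-forest conversion
  anticorrelate with population change;
* class-conditional Gaussian reflectance in six bands, with farmland
  given drier SWIR than forest (post-monsoon cropland) so its wetness
  sits mostly in the moderate band while NDVI stays high;
* smoothed-Gaussian soil fields spanning the nutrient/pH/OC
  breakpoints, sampled at 50 points on farmland; three stations near
  4000 mm/yr (monsoon-belt totals, which rank uniformly high against
  the printed precipitation breaks);
* 46 validation points on agricultural cells, sampled with probability
  increasing in the generated suitability score.

Each layer draws from its own sub-seed derived from the scene seed, so
adding a layer cannot shift the others and scenes are bit-reproducible.

What the generator does **not** emulate: radiometric realism, clouds
and shadows, mixed pixels, classifier error (LULC maps are exact by
construction), real census idiosyncrasies, and real geodesy. Passing
tests therefore demonstrate the *computational* correctness of the
pipeline under the assumed data structure, not classification accuracy
on real imagery.

## Problem sizes and defaults

The default scene is 120×120 cells at 30 m; unit tests use 60×60
scenes, and the per-cell engine oracle runs on ≤ 10×10 grids. The
acceptance script runs one full default scene end to end and a 20-scene
sign-recovery sweep. Key defaults: urbanization rate 0.35 and forest
reversion 0.30 per decade at the gradient extremes, road gradient scale
800 m, population coupling 0.6, band noise sd 0.02, soil correlation
length 600 m.

## Known limitations

* The score-to-class thirds rule and the nutrient thirds-on-mean rule
  are documented defaults for steps the source workflow leaves
  unstated; both are configurable.
* IDW with few, clustered samples produces bull's-eye artefacts, as
  IDW does; the tests check its contract (convexity, exactness at
  samples), not interpolation quality.
* Distance banding uses the polyline as given; no network distance.
* Area accounting assumes square cells on a planar grid; areas on a
  real ellipsoid would differ slightly.
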