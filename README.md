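# agrosuit

Agroforestry land-suitability mapping and land-use/land-cover (LULC)
change analysis on co-registered raster grids, written for land-systems
analysts who want the FAO rank-and-weight evaluation workflow as tested,
scriptable R functions rather than a chain of desktop-GIS operations.

The motivating setting is a mid-hill metropolitan region where valley
farmland is being lost to road-led urban expansion while remote terraced
farmland reverts to forest as hill wards depopulate. The package asks two
questions of such a landscape: *which of the remaining agricultural land
is suitable for agroforestry, and where has farmland gone?*

## The model

**Suitability overlay.** Eight criterion layers are derived from primitive
inputs — elevation and Horn-method slope from a DEM, NDVI
`(NIR − Red)/(NIR + Red)` and tasseled-cap wetness from six reflectance
bands, inverse-distance-weighted (IDW) surfaces for soil pH, organic
carbon, N/P/K and station precipitation. Each layer is ranked per cell
against FAO-style breakpoint tables (rank 3 = high, 2 = moderate,
1 = marginal; e.g. slope < 15° ranks 3, 15–35° ranks 2, > 35° ranks 1).
The three nutrient ranks combine with equal weights into a nutrient-status
layer. The composite score is the weighted sum

```
score(c) = Σ_i  w_i · rank_i(c) ,   Σ w_i = 1
```

with weights 25% (elevation), 12.5% (precipitation, wetness, NDVI, slope)
and 8.33% (nutrient status, organic carbon, pH), and is classified by
equal thirds of [1, 3] into S1 (highly suitable, score ≥ 7/3),
S2 (moderately suitable, ≥ 5/3) and S3 (marginally suitable), restricted
to classified agricultural land with rock/river/water surfaces excluded
as not suitable.

**Change accounting.** Dated LULC maps are cross-tabulated into a
transition matrix (rows = earlier date); conversion areas come from cell
counts × cell area. Conversion is summarized per ward and per
road-distance band, and ward population change is associated with
conversion areas by tie-corrected Kendall rank correlation (tau-b, with
exact permutation p-values at small n).

**Assessment.** Confusion matrices with overall accuracy, Cohen's kappa
and Landis–Koch agreement labels; validation-point overlay with half-up
percentages.

A seeded synthetic scene generator (`generate_scene()`) produces complete
miniature study areas — valley-to-hill DEM, highway, six-class LULC
evolving under road-proximal urbanization and road-distal forest
reversion coupled to ward population trajectories, class-dependent
spectral bands, autocorrelated soil fields, stations and validation
points — so the whole pipeline runs and is tested without any download.

## Worked example

```r
library(agrosuit)

bundle <- generate_scene(scene_config(seed = 1))   # 120x120 cells at 30 m
scene_to_files(bundle, "scene")                    # ASCII rasters + CSV + GeoJSON

suit <- run_suitability("scene", "out")
tot <- subset(suit$summary, zone == "TOTAL" & class %in% c("S1", "S2"))
tot[, c("class", "area_ha", "pct_of_zone_suitable")]
#>   class area_ha pct_of_zone_suitable
#>      S1  391.32             87.06    # highly suitable farmland
#>      S2   58.14             12.94    # moderately suitable

chg <- run_change("scene", "out")
conversion_area(chg$transition, 2, 1)   # agriculture -> forest: 280.08 ha
conversion_area(chg$transition, 2, 3)   # agriculture -> urban:  245.52 ha
chg$tau
#>     conversion    tau  p_value  n
#>    ag_to_urban  0.610  0.00019 20   # growing wards urbanize farmland
#>   ag_to_forest -0.222  0.17    20   # shrinking wards lose farmland to forest
```

The suitability shares say how the remaining 449 ha of farmland in the
scene split between high and moderate suitability; the tau row signs
reproduce the expected association pattern — agricultural conversion to
urban rises with ward population growth, conversion to forest falls with
it.

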