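# ridge2reef

Linked land-sea modeling of groundwater nutrient discharge and coral reef
communities, for ridge-to-reef management on high oceanic islands.

On small volcanic islands, submarine groundwater discharge (SGD) is a primary
vector carrying land-based nitrogen and phosphorus — from cesspools, septic
systems, injection wells and fertilized green space, on top of the natural
background — onto fringing reefs, where nutrient subsidies favor turf and
macroalgae over corals and crustose coralline algae (CCA). `ridge2reef`
implements the whole chain from rainfall to reef as a reproducible pipeline,
so that reef cells vulnerable to land-based nutrients can be flagged and
traced back to the land parcels that feed them.

The stages, each a plain R function over a small set of containers
(`raster_grid`, `feature_set`, `driver_stack`):

1. **Recharge & groundwater flow** — per-cell water balance
   `R = P + I + OSDS − DR − AE − ΔSS`; steady single-layer flow
   `∇·(T∇h) = −w` by sparse 5-point finite differences with a fixed coastal
   head; domain budget `ΔGW = R + Inj − ET − Str − Q − Cstl = 0` closed for
   coastal discharge.
2. **Nutrient loading** — background flux as zone concentration × recharge
   volume (`flux = conc × vol × 10⁻³` kg yr⁻¹); anthropogenic flux from a
   per-class loading table (cesspool, septic, injection well, lawn, golf),
   rasterized with exact polygon-cell clipping; background and human-derived
   fluxes kept separate end to end.
3. **Flow tubes** — reverse particle tracking from shoreline pour points
   (200 m spacing) partitions the coastal strip into tubes; zone budgets sum
   water and nutrients per tube, conservatively.
4. **Coastal plumes** — each pour-point loading decays over the reef as
   `W = L_p · e^(−c²/D_c)` along a Dijkstra least-accumulative-cost surface
   (depth, distance from shore, wave power), cut off 1 km from shore.
5. **Marine drivers** — slope, aspect statistics, BPI (60/240 m), planar and
   profile curvature, rugosity, distance to shore at 60 m resolution.
6. **Reef models** — boosted regression trees (Gaussian deviance; sqrt cover,
   fourth-root biomass scales) with 10-fold CV tree selection, PDE / CV PDE,
   relative influence, partial-dependence curves, prediction maps, Moran's I
   residual checks and observed-vs-predicted regression; benthic models feed
   the fish models.
7. **Ordination** — distance-based redundancy analysis (Euclidean ⇒ RDA) of
   the indicator matrix on the pruned driver matrix.
8. **Prioritization** — threshold overlay (shallow depth, above-mean benthic
   cover, upper-tercile nutrients, lower-tercile wave power) flags vulnerable
   reef cells and ranks the flow tubes upstream of them.

A synthetic-site generator (`generate_site()`, presets `"wet"` and `"dry"`)
builds complete ground-truthed inputs — climate and transmissivity rasters,
bathymetry and wave power, shoreline, recharge zones, source inventories, and
surveys drawn from known driver-response functions — so every stage is
testable end to end without external data.

## Worked example

```r
library(ridge2reef)

# per-class loading arithmetic: a cesspool leaching 435 m3/yr at 87 mg/L N
flux_from_concentration(87, 435)
#> [1] 37.845        # kg N per cesspool per year

# full pipeline on the synthetic windward preset (40 x 40 land cells)
res <- run_pipeline(pipeline_config(preset = "wet", size = 40, seed = 1))
print(res)
#> <pipeline_result> wet preset, seed 1
#> <water_budget> (m3/yr)
#>   R     4.76077e+06
#>   Inj   0
#>   ET    0
#>   Str   455088
#>   Q     0
#>   Cstl  4.30568e+06
#>   9 flow tubes; D_c = 9617; 150 surveys
#>   model evaluation:
#>    indicator   PDE CV_PDE obs_pred_r2 obs_pred_p moran_i_resid moran_p_resid
#> 1        cca 0.982  0.921       0.960  1.65e-105      -0.15792         0.008
#> 2      coral 0.985  0.869       0.959  9.43e-105      -0.09151         0.086
#> ...
#>   ordination axis 1: 81.5% of fitted variation
#>   vulnerable reef cells: 61

head(res$priority, 2)
#>   id flagged_cells n_flux_anthropogenic p_flux_anthropogenic rank
#> 1  6            45               1447.7                341.5    1
#> 2  5            11                843.5                192.4    2
```

Reading the output: 4.76 million m³ of groundwater is recharged per year, of
which 4.31 million reaches the coast after stream capture (`Cstl`), split
across 9 flow tubes. The reef models explain 87–93% of cross-validated
deviance on the synthetic surveys (whose true signal is known), their
residuals show no strong positive spatial autocorrelation, and 61 shallow
reef cells meet every vulnerability criterion — most attributed to tube 6,
the one carrying the largest human-derived nitrogen flux (1,448 kg yr⁻¹), so
the cesspools inside that tube would be the first management target.

`res$predictions` holds the indicator maps, `res$terrestrial$plumes` the SGD
plume rasters, and `run_pipeline(... , out_dir = "artifacts/")` writes every
artifact (ASCII grids, GeoJSON, CSV) with a checksum manifest; identical
configurations rerun bit-identically. A thin CLI lives at
`inst/scripts/r2r` (`r2r synth`, `r2r run`).

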