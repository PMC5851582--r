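---
title: "A linked land-sea model of groundwater nutrient discharge and reef communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A linked land-sea model of groundwater nutrient discharge and reef communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridge2reef)
```

## The problem

On small, steep oceanic islands land and sea are tightly coupled: rainfall
recharges a thin coastal aquifer, the aquifer discharges through the seafloor
as submarine groundwater discharge (SGD), and the SGD carries dissolved
nitrogen and phosphorus from natural weathering and from human activity
(cesspools, septic tanks, injection wells, fertilized lawns and golf courses)
onto fringing coral reefs. Nutrient subsidies favor turf and macroalgae over
reef-building corals and crustose coralline algae (CCA), so the question a
manager needs answered is spatial: *which reef cells are vulnerable to
land-based nutrients, and which land parcels feed them?*

`ridge2reef` implements that chain of reasoning as a reproducible pipeline of
coupled models at desk scale. Every stage is an ordinary R function over a
small set of containers (a planar `raster_grid`, a `feature_set` of vector
features, a `driver_stack` of co-registered reef layers), and a synthetic-site
generator supplies complete, ground-truthed inputs so the whole chain can be
exercised and tested without any proprietary data.

## Model chain

### Recharge and the groundwater budget

Per-cell recharge depth follows the long-term water balance

> R = P + I + OSDS − DR − AE − ΔSS,

with precipitation `P`, irrigation `I`, effluent leaching from onsite sewage
disposal systems `OSDS`, direct runoff `DR` taken as a fixed fraction of
rainfall (54% for the wet preset), actual evapotranspiration `AE`, and
soil-storage change `ΔSS` (zero by default: storage averages out over the
long term). Negative balances are clipped to zero and counted. The domain
budget closes as

> ΔGW = R + Inj − ET − Str − Q − Cstl = 0,

solving for coastal discharge `Cstl` as the residual; `ET` from the aquifer is
zero whenever the water table is deeper than the 1.5 m extinction depth, and
stream baseflow `Str` is anchored at a gauged 0.26 m³ s⁻¹ reference discharge
scaled by relative watershed area.

The flow model is deliberately the simplest one that preserves what the rest
of the chain consumes — the *distribution of discharge along the shoreline*:
a single-layer steady-state transmissivity model, `∇·(T∇h) = −w`, discretized
with 5-point finite differences (harmonic-mean face transmissivities), a
Dirichlet equivalent-freshwater head (0 m) at the coastal cells standing in
for the density-corrected coastal boundary, no-flow lateral and inland
boundaries, and a direct sparse solve. The scheme is exact for quadratic
water tables, so the classic 1-D strip solution is reproduced to machine
precision; the per-cell divergence residual is reported with the solution and
the test suite holds global mass balance to better than 10⁻⁶ relative.
Transient flow, the unsaturated zone and density-dependent flow are out of
scope. No field transmissivity data are bundled; the synthetic presets use
5×10⁵ (wet) and 2×10⁵ m² yr⁻¹ (dry), chosen once to give realistic 1–5 m
coastal heads.

### Nutrient loading

Background loading converts each recharge zone's representative groundwater
concentration (mg L⁻¹) through the cell's recharge volume:
flux = conc × volume × 10⁻³ kg yr⁻¹. Anthropogenic loading uses a per-class
table (cesspool, septic, injection well, lawn, golf) carrying both the
concentration/volume parameters and the authoritative per-unit or per-hectare
flux values the pipeline consumes; a per-residence wastewater volume of
435 m³ yr⁻¹ (three bedrooms, 1.5 persons per bedroom) underlies the OSDS
classes. Points add their per-unit flux to the containing cell; polygons are
clipped exactly against the cell rectangles (Sutherland–Hodgman), so domain
totals are independent of grid resolution to 10⁻⁹ relative. Background and
anthropogenic rasters are kept separate end to end, which is what makes
"human-derived fraction" a computable quantity downstream. Phosphorus
sorption is exposed as a per-class delivery factor (default 1: no sorption
for wastewater below the soil zone); soil chemistry itself is not modeled.

### The land-sea link: flow tubes

Pour points are placed every 200 m of shoreline arc length (first at half a
spacing). From each pour point a particle is traced *against* the Darcy
velocity field (fixed-step midpoint Runge–Kutta over bilinearly interpolated
cell-center velocities) until it leaves the active area, stalls, or hits the
step cap. The band between two adjacent reverse paths — closed by the
shoreline arc between their seeds and clipped to the coastal strip (1,000 m
inland for the wet preset, 3,500 m for the dry) — is a *flow tube*; every
strip cell belongs to exactly one tube (cells on a boundary line go to the
tube on the left looking inland; strip cells that fall outside all bands,
e.g. beyond the outermost paths, attach to the nearest assigned tube and are
logged). Tube exchange is hardened to exactly zero so the zone budget is
conservative by construction: per tube, water and the four nutrient fluxes
are summed over member cells, and inflow from upslope of the strip is
allocated across tubes proportionally to their coastal water flux (an
explicit convention; proportional-to-width is available). Tube sums equal
strip totals plus upslope inflow exactly.

### Coastal plumes

Each tube discharges its water and nutrients at its pour point, and the
loading spreads over the reef as a decaying plume:

> W = L_p · exp(−c² / D_c),

where `c` is the least accumulative cost from the pour point over a composite
impedance surface — water depth, distance from shore and wave power, each
min-max normalized and combined with equal weights by default (the weighting
is a declared free parameter) — computed by Dijkstra's algorithm on the
8-neighbor cell graph (edge weight = mean endpoint cost × center distance,
diagonals ×√2). Cells beyond 1,000 m from the shoreline receive zero. `D_c`
is defined only as the cost "equivalent to" that cutoff, so the package
adopts an explicit calibration: the least cost with which the cutoff distance
band can be reached, averaged over pour points, satisfies c² = 9·D_c — the
kernel has decayed to e⁻⁹ (≈0.01%) at the cutoff. The kernel form is the
default; an optional mass-conserving mode rescales each plume so its cell sum
equals the pour-point loading. The model is diffusive by design: it wraps
around coastal features but carries no advection, tides or salinity mixing.

### Marine drivers

From bathymetry and wave power at 60 m resolution the stack derives the
standard benthic-terrain metrics: Horn-style slope and downslope aspect from
a 3×3 quadratic surface fit; bathymetric position index (BPI, center minus
circular-neighborhood mean, center excluded) at 60 m and 240 m radii;
profile and planar curvature (second directional derivatives along and
across the gradient; zero where the gradient is degenerate); rugosity as the
true-to-planimetric area ratio of the eight-triangle fan around each cell
(exactly 1 when flat, 1/cos θ on a tilted plane); and circular statistics of
aspect (northness = cos, eastness = sin of the circular mean; circular SD
√(−2 ln R̄)). Distance to shore is the exact point-to-segment distance. Edge
cells use replicated padding, so metrics there are one-sided; analytic
checks in the tests are made on window interiors. Finer bathymetry is
aggregated to 60 m by block means before metrics.

### Reef models

Each of eight indicators — CCA, coral, turf and macroalgae percent cover;
browser, grazer, scraper and piscivore biomass — is modeled independently by
boosted regression trees under Gaussian deviance, on the square-root
(benthic) or fourth-root (fish) scale. Drivers are sampled at survey
locations by bilinear interpolation (nodata neighbors renormalized). The
fitting surface is gbm-style stagewise least-squares boosting with
shrinkage and per-tree bagging, run on an xgboost backend (single thread,
seeded, unregularized trees) with the tree count chosen at the 10-fold
cross-validated deviance minimum and the (learning rate, tree complexity,
bag fraction) combination chosen by maximum cross-validated percent deviance
explained (CV PDE). PDE and CV PDE are reported on the transformed scale.
The default search grid is lr ∈ {0.05, 0.01} × tc ∈ {2, 3} ×
bag ∈ {0.5, 0.75} with up to 1,500 trees and early stopping — a compact grid
that covers the useful range at the package's data sizes (a few hundred
surveys); it is config-exposed and can be widened freely. Relative influence
is the per-driver share of split gain, normalized to 100; response curves
are partial-dependence marginalizations over the training rows. Fish models
take the *observed* benthic covers as extra predictors at fit time and the
*predicted* benthic maps at prediction time, enforcing the benthic-then-fish
ordering. Predictions are back-transformed and clipped (cover to [0, 100],
biomass to ≥0), with nodata propagated from any missing driver. Residual
spatial autocorrelation is checked with Moran's I under row-standardized
distance-band weights (default band: 3× the median nearest-neighbor
distance, widened to the maximum nearest-neighbor distance so no point is
neighborless) with a two-sided permutation p-value; observed-versus-predicted
agreement by ordinary least squares (R², slope, p).

### Ordination and prioritization

The indicator matrix (transformed, z-scored) is ordinated on the z-scored
driver matrix. With the Euclidean resemblance this distance-based redundancy
analysis reduces to redundancy analysis proper, computed via `vegan::rda`;
drivers correlated above |r| = 0.7 are pruned greedily in column order (the
later column of an offending pair is dropped — the order is documented
because it is a genuine free choice). Each constrained axis reports its
percent of fitted and of total variation; a fitted fraction above 70% is
flagged as a good fit, not enforced.

Vulnerability overlays the prediction maps and driver layers with
site-specific criteria: depth shallower than 5 m (bleaching exposure),
above-site-mean cover of the site's indicator benthic groups (coral,
macroalgae and turf for the wet preset; coral, CCA and turf for the dry),
nutrient flux above the upper tercile, and — where active — wave power below
the lower tercile (limited mixing). The wet preset uses the N and wave
criteria (P inactive); the dry preset uses N and P (wave inactive). All
criteria combine conjunctively and the per-criterion masks are returned so
the flag set is verifiable as their intersection. Each flagged cell is then
attributed to the flow tube contributing the largest nutrient plume at that
cell, and tubes are ranked by anthropogenic flux, then flagged-cell count,
then id — a deterministic priority list of land areas for nutrient
management.

## The synthetic sites

`generate_site()` builds two contrasting presets on an n×n grid of 50 m land
cells with a sinusoidal shoreline (one embayment, so flow lines converge into
a bay) and a 60 m reef grid reaching ~1.5 km offshore:

* **wet** (windward): rainfall around 4.04 m yr⁻¹ with an inland orographic
  gradient, 54% direct runoff, uniform background concentrations (0.50 N,
  0.20 P mg L⁻¹), 136 coastal residences (99 cesspools + 37 septic systems)
  and 6 ha of lawn, two gauged-stream equivalents via the scaled baseflow
  term, high wave power, 1,000 m flow-tube strip. Generated recharge falls
  within 0.11–4.97 m yr⁻¹.
* **dry** (leeward): rainfall 0.26–1.35 m yr⁻¹, 30% runoff fraction, four
  background zones (upland/lowland on each side of a rift line, N up to
  2.70 mg L⁻¹), 193 cesspool residences, lawns, a golf course and a
  160,600 m³ yr⁻¹ injection well, no streams, low wave power, 3,500 m strip.
  Generated recharge falls within 0.04–0.69 m yr⁻¹.

Houses aggregate into a few coastal communities (Gaussian alongshore
kernels, cells drawn without replacement), which both mirrors real coastal
development and gives tubes distinct anthropogenic/background flux mixes.
Lawn and golf polygon areas are scaled to the desk-scale domain footprint
(the real golf course would cover half of it); per-hectare rates are
unchanged. The seafloor combines a preset-specific shelf profile with smooth
bumps and *independent* patchy fine-scale roughness, so habitat complexity
(rugosity) is not slaved to habitat topography (slope).

Surveys are generated from known smooth responses: each indicator's
transformed-scale truth is an intercept plus 2–4 terms in z-scored drivers
(the leading term saturating through tanh, the rest linear), fish responses
additionally consuming the benthic truth values; Gaussian noise is added on
the transformed scale (default SD = 25% of the signal SD), then values are
clipped and back-transformed. Plume drivers enter the truth functions on the
log1p scale — their raw fields span orders of magnitude, and an ecological
response to an exponentially decaying subsidy is smooth in its log. The
truth record (active drivers, coefficients, noise, seed) rides along as an
attribute, which is what the recovery tests and the acceptance script
consume.

What the generator does *not* emulate: real rainfall geostatistics, wave
hindcasting, reef zonation (fore-reef/back-reef structure), survey
stratification by habitat, and observation error models beyond additive
Gaussian noise. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that known signal of realistic strength is
recovered — not that the models would attain any particular skill on field
data.

## Numerical choices and degenerate inputs

* Grid indexing is row-major from the lower-left corner, cell centers at
  `origin + (i − 0.5)·cellsize`, half-open cell intervals for point-in-cell
  tests; nodata propagates through all arithmetic.
* The head solve is a direct sparse factorization (no iteration tolerance to
  tune); the divergence residual is computed and carried on the solution.
* Dijkstra edge weights use the mean of endpoint costs; nodata cells are
  impassable; unreachable cells stay nodata.
* A constant cost driver is dropped with a warning and the remaining weights
  renormalized; an all-constant composite is an error.
* Constant responses (SST = 0), n < 30, or fewer than 2 predictors are
  errors in `fit_brt()`; constant values or user bands that leave a point
  neighborless are errors in `morans_i()`.
* Ties in tube assignment (cell center exactly on a path) go to the left
  tube; tied priority ranks break by tube id.
* All stochastic steps (site fields, source placement, survey sampling and
  noise, CV folds, bagging, permutations) derive from explicit integer
  seeds; identical configurations reproduce artifacts bit-identically,
  checksummed in the run manifest.

## Problem sizes

The package's own test and example runs use 30–40 cell land grids (≈2–4 km
of coastline, 9–13 flow tubes), 60–300 surveys, and compact BRT grids; a
full end-to-end synthetic run at these sizes completes in seconds to a few
minutes on one core. All sizes are configuration parameters.

## Known limitations

* The three plume layers (freshwater, N, P) share one decay kernel per pour
  point and differ only through per-tube loading mixes, so they are strongly
  collinear (r > 0.95 in the synthetic sites, and unavoidably high anywhere).
  Relative influence dilutes across such siblings; the ordination stage
  prunes them at |r| > 0.7, and influence-based driver identification should
  be read at the group level for the plume trio.
* Site-level literature quantities (absolute discharge volumes, human-derived
  fractions, site PDE ranges) depend on full-scale rasters and surveys and
  are not reproduced at desk scale; the package's claims are the worked
  per-class flux values, the fixture census, and the property suite the
  tests and `scripts/acceptance.R` compute.
* The plume model is diffusive only; advection, tides, and biogeochemical
  transformation (denitrification, anammox, P sorption dynamics) are out of
  scope.
* The flow model is steady-state and single-layer; heads near the coast
  stand in for a density-corrected interface.
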