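Package: ridge2reef
Title: Linked Land-Sea Modeling of Groundwater Nutrient Discharge and Coral
    Reef Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale linked land-sea modeling pipeline for high oceanic
    islands. Computes groundwater recharge and a steady-state water budget,
    converts land cover/use inventories (cesspools, septic systems, injection
    wells, lawns, golf courses) and background aquifer concentrations into
    nitrogen and phosphorus flux, partitions the coastal aquifer into flow
    tubes discharging at shoreline pour points, diffuses each pour point's
    water and nutrient flux over the reef with a least-accumulative-cost decay
    model, derives bathymetric terrain drivers (BPI, slope, curvature,
    rugosity, aspect statistics), calibrates boosted-regression-tree models of
    reef benthic cover and fish biomass, ordinates the indicator matrix on the
    driver matrix, and overlays threshold criteria to flag vulnerable reef
    cells and rank the upstream land areas for nutrient management. Includes a
    synthetic-site generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    vegan,
    xgboost,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
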