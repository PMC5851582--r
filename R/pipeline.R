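#' Pipeline configuration
#'
#' Assembles every tunable the end-to-end run consumes. Defaults reproduce
#' the synthetic study conditions at desk scale; any element can be
#' overridden. The BRT grid here is deliberately a single small combination
#' so a full run stays interactive; use [brt_config()] defaults for a real
#' calibration search.
#'
#' @param preset `"wet"` or `"dry"` synthetic preset.
#' @param size land grid dimension (cells).
#' @param seed root seed; every stochastic stage derives its stream from it.
#' @param n_surveys reef surveys to generate.
#' @param noise_frac survey noise fraction (see [generate_surveys()]).
#' @param tube_spacing pour-point spacing (m).
#' @param plume_conserve mass-conserving plume mode.
#' @param brt a [brt_config()].
#' @param reference_watershed_ha area anchoring the stream-baseflow scaling.
#' @param out_dir artifact directory or `NULL` to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "wet", size = 40, seed = 1,
                            n_surveys = 150, noise_frac = 0.25,
                            tube_spacing = 200, plume_conserve = FALSE,
                            brt = brt_config(lr = 0.05, tc = 2, bag = 0.75,
                                             n_trees_max = 300, folds = 10),
                            reference_watershed_ha = 6130,
                            out_dir = NULL) {
  structure(list(preset = preset, size = size, seed = seed,
                 n_surveys = n_surveys, noise_frac = noise_frac,
                 tube_spacing = tube_spacing, plume_conserve = plume_conserve,
                 brt = brt, reference_watershed_ha = reference_watershed_ha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file holding any subset of the fields above.
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, v[setdiff(names(v), "brt")])
  if (!is.null(v$brt)) cfg$brt <- do.call(brt_config, v$brt)
  cfg
}

#' Coastal fixed-head cells of a land grid
#'
#' Active land cells 4-adjacent to an inactive (ocean) cell; these get the
#' Dirichlet equivalent-freshwater head.
#'
#' @param grid land [raster_grid()] (ocean nodata).
#' @return logical matrix.
#' @export
coastal_cells <- function(grid) {
  act <- !is.na(grid$values)
  nr <- nrow(act); nc <- ncol(act)
  nb_inactive <- matrix(FALSE, nr, nc)
  nb_inactive[-1, ] <- nb_inactive[-1, ] | !act[-nr, ]
  nb_inactive[-nr, ] <- nb_inactive[-nr, ] | !act[-1, ]
  nb_inactive[, -1] <- nb_inactive[, -1] | !act[, -nc]
  nb_inactive[, -nc] <- nb_inactive[, -nc] | !act[, -1]
  act & nb_inactive
}

#' Run the terrestrial half of the framework
#'
#' Recharge, steady groundwater flow, water budget, nutrient loading, flow
#' tubes, zone budgets and coastal plumes for a site bundle. Stream baseflow
#' is scaled by the domain's land area relative to the reference watershed
#' and removed from the recharge field proportionally, so the water reaching
#' the flow tubes equals the budget's coastal discharge; injection-well water
#' is added at the well's flow tube.
#'
#' @param bundle a `site_bundle`.
#' @param config a [pipeline_config()].
#' @return list: `recharge`, `head`, `flow`, `budget` (water_budget),
#'   `tubes`, `tube_budget`, `plumes`, `stack` (driver stack incl. plume
#'   layers), `cost`, `dist_shore_reef`, `bg` and `anth` flux rasters.
#' @export
run_terrestrial <- function(bundle, config = pipeline_config()) {
  a <- bundle$rainfall$cell_size
  osds <- osds_recharge(bundle$sources, bundle$rainfall)
  recharge <- compute_recharge(bundle$rainfall, bundle$actual_et, OSDS = osds,
                               DR_fraction = bundle$params$dr_fraction)
  land_ha <- sum(!is.na(recharge$values)) * a^2 / 1e4
  R_tot <- sum(recharge$values * a^2, na.rm = TRUE)
  Str <- if (bundle$params$stream_area_fraction > 0)
    stream_baseflow(bundle$params$stream_area_fraction *
                      land_ha / config$reference_watershed_ha) else 0
  Inj <- bundle$params$injection_volume
  budget <- domain_water_budget(R = R_tot, Inj = Inj, Str = Str)

  # water actually reaching the coast: recharge net of stream capture
  f_str <- if (R_tot > 0) 1 - Str / R_tot else 1
  recharge_eff <- grid_with(recharge, recharge$values * f_str, units = "m.yr-1")

  fixed <- coastal_cells(recharge)
  head <- solve_steady_head(recharge_eff, bundle$transmissivity, fixed)
  flow <- darcy_flow(head, bundle$transmissivity)

  bg <- background_flux(bundle$recharge_zones, recharge_eff)
  anth <- rasterize_sources(bundle$sources, recharge)

  pp <- place_pour_points(bundle$shoreline, config$tube_spacing)
  paths <- trace_flowpaths(flow, pp)
  tubes <- delineate_flow_tubes(paths, bundle$shoreline, recharge,
                                bundle$params$inland_extent)
  water <- grid_with(recharge_eff, recharge_eff$values * a^2, units = "m3.yr-1")
  strip_sum <- function(r, inside) {
    v <- r$values; v[is.na(v)] <- 0
    sum(v[inside])
  }
  in_strip <- tubes$strip
  upslope <- list(
    water = strip_sum(water, !in_strip),
    n_bg = strip_sum(bg$n, !in_strip), p_bg = strip_sum(bg$p, !in_strip),
    n_anth = strip_sum(anth$n, !in_strip), p_anth = strip_sum(anth$p, !in_strip))
  tb <- zone_budget(tubes, water, bg$n, anth$n, bg$p, anth$p, upslope = upslope)
  # injection water discharges through the tube nearest the well
  if (Inj > 0) {
    iw <- Filter(function(f) identical(f$attributes$class, "injection_well"),
                 bundle$sources$features)
    if (length(iw)) {
      p <- iw[[1]]$geometry$coords
      k <- which.min((tb$x - p[1])^2 + (tb$y - p[2])^2)
      tb$water_flux[k] <- tb$water_flux[k] + Inj
    }
  }

  dshore_reef <- mask_like(distance_to_shore(bundle$shoreline, bundle$bathymetry),
                           bundle$bathymetry)
  cost <- cost_surface(bundle$bathymetry, dshore_reef, bundle$wave_power)
  plumes <- stack_plumes(tb, cost, dshore_reef,
                         max_shore_distance = bundle$params$max_shore_distance,
                         conserve = config$plume_conserve)
  stack <- build_driver_stack(bundle$bathymetry, bundle$wave_power,
                              bundle$shoreline, plumes = plumes)
  list(recharge = recharge, recharge_eff = recharge_eff, head = head,
       flow = flow, budget = budget, bg = bg, anth = anth,
       pour_points = pp, paths = paths, tubes = tubes, tube_budget = tb,
       cost = cost, dist_shore_reef = dshore_reef, plumes = plumes,
       stack = stack)
}

benthic_names <- function() c("cca", "coral", "turf", "macroalgae")
fish_names <- function() c("browser", "grazer", "scraper", "piscivore")

#' Run the linked land-sea pipeline end to end
#'
#' Executes every stage in order - recharge, groundwater flow, nutrient
#' loading, flow tubes, coastal plumes, marine drivers, synthetic surveys,
#' BRT calibration (benthic first, then fish with observed benthic
#' predictors), prediction maps (fish maps consume the predicted benthic
#' layers), ordination, and vulnerability prioritization - and optionally
#' writes all artifacts with a checksum manifest. Re-running with an
#' identical configuration reproduces every artifact bit-identically.
#'
#' @param config a [pipeline_config()], or a YAML path for
#'   [read_pipeline_config()].
#' @return list of class `pipeline_result` with the bundle, every stage
#'   output, `models`, `predictions`, `evaluation` (per-indicator PDE,
#'   CV PDE, observed-vs-predicted R2 and Moran's I on residuals),
#'   `ordination`, `criteria`, `vulnerability`, `priority`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  bundle <- generate_site(config$preset, config$size, config$seed)
  terr <- run_terrestrial(bundle, config)
  stack <- terr$stack
  surveys <- generate_surveys(bundle, stack, config$n_surveys,
                              seed = config$seed + 1,
                              noise_frac = config$noise_frac)
  X0 <- attr(surveys, "drivers")
  models <- list(); predictions <- list(); evaluation <- list()
  pred_stack <- stack
  for (nm in benthic_names()) {
    y <- transform_response(surveys[[nm]], "sqrt")
    models[[nm]] <- fit_brt(X0, y, config$brt, seed = config$seed + 2,
                            response = nm, transform = "sqrt", upper = 100)
    predictions[[nm]] <- predict_map(models[[nm]], stack)
    pred_stack[[nm]] <- predictions[[nm]]
  }
  Xf <- cbind(X0, as.data.frame(surveys[, benthic_names()]))
  for (nm in fish_names()) {
    y <- transform_response(surveys[[nm]], "fourth_root")
    models[[nm]] <- fit_brt(Xf, y, config$brt, seed = config$seed + 2,
                            response = nm, transform = "fourth_root")
    predictions[[nm]] <- predict_map(models[[nm]], pred_stack)
  }
  for (nm in names(models)) {
    pm <- predictions[[nm]]
    pr <- vapply(seq_len(nrow(surveys)), function(r)
      bilinear_at(pm$values, pm, c(surveys$x[r], surveys$y[r])), 0)
    ok <- is.finite(pr)
    ov <- obs_vs_pred(surveys[[nm]][ok], pr[ok])
    resid <- models[[nm]]$y - models[[nm]]$fitted
    mi <- morans_i(resid, cbind(surveys$x, surveys$y), seed = config$seed + 3)
    evaluation[[nm]] <- data.frame(
      indicator = nm, PDE = models[[nm]]$PDE, CV_PDE = models[[nm]]$CV_PDE,
      obs_pred_r2 = ov$r2, obs_pred_p = ov$p,
      moran_i_resid = mi$I, moran_p_resid = mi$p)
  }
  evaluation <- do.call(rbind, evaluation)
  rownames(evaluation) <- NULL

  Y <- cbind(sapply(benthic_names(), function(nm) transform_response(surveys[[nm]], "sqrt")),
             sapply(fish_names(), function(nm) transform_response(surveys[[nm]], "fourth_root")))
  colnames(Y) <- c(benthic_names(), fish_names())
  ordination <- dbrda_reef(Y, X0)

  criteria <- derive_thresholds(stack, predictions, site = bundle$preset)
  vulnerability <- classify_vulnerable(stack, predictions, criteria)
  priority <- match_priority_tubes(vulnerability, terr$tube_budget,
                                   terr$plumes$per_tube)

  res <- list(config = config, bundle = bundle, terrestrial = terr,
              stack = stack, surveys = surveys, models = models,
              predictions = predictions, evaluation = evaluation,
              ordination = ordination, criteria = criteria,
              vulnerability = vulnerability, priority = priority)
  if (!is.null(config$out_dir)) res$manifest <- write_artifacts(res, config$out_dir)
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$config$preset, "preset, seed", x$config$seed, "\n")
  print(x$terrestrial$budget)
  cat(sprintf("  %d flow tubes; D_c = %.4g; %d surveys\n",
              nrow(x$terrestrial$tube_budget), x$terrestrial$plumes$D_c,
              nrow(x$surveys)))
  cat("  model evaluation:\n")
  print(x$evaluation, digits = 3)
  cat(sprintf("  ordination axis 1: %.1f%% of fitted variation\n",
              x$ordination$pct_fitted[1]))
  cat(sprintf("  vulnerable reef cells: %d\n", x$vulnerability$n_flagged))
  invisible(x)
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  terr <- res$terrestrial
  write_site(res$bundle, file.path(out_dir, "site"))
  rasters <- c(list(recharge = terr$recharge, head = terr$head$head,
                    cost = terr$cost,
                    freshwater = terr$plumes$freshwater,
                    n_plume = terr$plumes$n_flux, p_plume = terr$plumes$p_flux,
                    vulnerability = res$vulnerability$flags),
               stats::setNames(res$predictions,
                               paste0("pred_", names(res$predictions))))
  for (nm in names(rasters))
    write_ascii_grid(rasters[[nm]], file.path(out_dir, paste0(nm, ".asc")))
  utils::write.csv(terr$tube_budget, file.path(out_dir, "tube_budget.csv"),
                   row.names = FALSE)
  utils::write.csv(res$surveys, file.path(out_dir, "surveys.csv"),
                   row.names = FALSE)
  utils::write.csv(res$evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(res$priority, file.path(out_dir, "priority_tubes.csv"),
                   row.names = FALSE)
  budget_df <- as.data.frame(res$terrestrial$budget[c("R", "Inj", "ET", "Str",
                                                      "Q", "Cstl")])
  utils::write.csv(budget_df, file.path(out_dir, "water_budget.csv"),
                   row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    seed = res$config$seed, preset = res$config$preset, size = res$config$size,
    plume_conserve = res$config$plume_conserve,
    coastal_discharge_m3yr = res$terrestrial$budget$Cstl,
    tube_water_total_m3yr = sum(res$terrestrial$tube_budget$water_flux),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
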