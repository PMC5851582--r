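#' Generate a complete synthetic land-sea site
#'
#' Builds all inputs the pipeline consumes for one of two contrasting
#' presets with known ground truth:
#'
#' * `"wet"` - a windward high-rainfall site: rainfall drawn around
#'   4.04 m yr-1 with an inland orographic gradient, direct runoff at 54% of
#'   rainfall, uniform background concentrations (0.50 mg L-1 N,
#'   0.20 mg L-1 P), 136 coastal residences (99 cesspools, 37 septic
#'   systems) plus 6 ha of lawn, high wave power, and a 1,000 m flow-tube
#'   strip. Recharge falls within 0.11-4.97 m yr-1.
#' * `"dry"` - a leeward low-rainfall site: rainfall 0.26-1.35 m yr-1, four
#'   background-concentration zones (upland/lowland on each side of a rift
#'   line), 193 cesspool residences, lawns, a golf course and a
#'   wastewater injection well, low wave power, and a 3,500 m strip.
#'   Recharge falls within 0.04-0.69 m yr-1.
#'
#' The land domain is an `size` x `size` grid of 50 m cells with a sinusoidal
#' shoreline (one embayment, so flow lines converge at a bay) along the
#' southern edge; the reef domain is a co-located 60 m grid extending about
#' 1.5 km offshore. Coastal development is concentrated in the coastal
#' strip. All fields are deterministic given `(preset, size, seed)`.
#'
#' @param preset `"wet"` or `"dry"`.
#' @param size land grid dimension in cells (>= 20).
#' @param seed integer seed.
#' @return a `site_bundle` list: rasters `rainfall`, `actual_et`,
#'   `transmissivity` (land, 50 m), `bathymetry`, `wave_power` (reef, 60 m);
#'   feature sets `shoreline`, `recharge_zones`, `sources`; `params`
#'   (preset constants: `dr_fraction`, `inland_extent`, `tube_spacing`,
#'   `injection_volume`, `stream_area_fraction`); `truth` (per-indicator
#'   generative response spec and seed).
#' @export
generate_site <- function(preset = c("wet", "dry"), size = 40, seed = 1) {
  preset <- match.arg(preset)
  if (size < 20) stop("size must be >= 20 cells")
  a <- 50                                   # land cell size, m
  W <- size * a; H <- size * a
  if (W < 2 * 200) stop("domain too small to host >= 2 flow tubes")
  set.seed(seed)

  y0 <- 0.15 * H; amp <- 0.05 * H
  shore_fun <- function(x) y0 + amp * sin(2 * pi * (x - 0.25 * W) / W)
  sx <- seq(0, W, by = a / 2)
  shoreline <- feature_set(list(list(
    geometry = list(type = "LineString", coords = cbind(sx, shore_fun(sx))),
    attributes = list(name = "shoreline"))))

  # ---- land rasters -------------------------------------------------------
  xc <- (seq_len(size) - 0.5) * a
  yc <- (seq_len(size) - 0.5) * a
  ys <- shore_fun(xc)
  land <- outer(yc, ys, `>`)                # [row i, col j]: y_i > y_sh(x_j)
  u <- outer(yc, ys, function(y, s) pmin(pmax((y - s) / (H - y0), 0), 1))

  n1 <- smooth_noise(size, size, sigma = 3)
  n2 <- smooth_noise(size, size, sigma = 3)
  n3 <- smooth_noise(size, size, sigma = 2)
  if (preset == "wet") {
    P <- 2.3 + 3.6 * u + 0.12 * n1
    AE <- pmin(pmax(0.5 + 0.08 * n2, 0.34), 0.66)
    Tm <- 5e5 * exp(0.1 * n3)
    drf <- 0.54
  } else {
    P <- 0.30 + 0.75 * u + 0.02 * n1
    AE <- 0.25 * P + 0.01 * n2
    Tm <- 2e5 * exp(0.1 * n3)
    drf <- 0.30
  }
  P <- pmax(P, 0.01); AE <- pmax(AE, 0)
  mk <- function(m, units) {
    m[!land] <- NA_real_
    raster_grid(m, a, c(0, 0), units = units)
  }
  rainfall <- mk(P, "m.yr-1"); actual_et <- mk(AE, "m.yr-1")
  transmissivity <- mk(Tm, "m2.yr-1")

  # ---- reef rasters (60 m) ------------------------------------------------
  ar <- 60
  nxr <- floor(W / ar)
  ylo <- -1500
  nyr <- floor((y0 + amp + 2 * ar - ylo) / ar)
  xr <- (seq_len(nxr) - 0.5) * ar
  yr <- ylo + (seq_len(nyr) - 0.5) * ar
  ysr <- shore_fun(xr)
  ocean <- outer(yr, ysr, `<`)
  doff <- outer(yr, ysr, function(y, s) pmax(s - y, 0))   # offshore distance
  nb <- smooth_noise(nyr, nxr, sigma = 2)
  nb2 <- smooth_noise(nyr, nxr, sigma = 1.5)
  nw <- smooth_noise(nyr, nxr, sigma = 3)
  # patchy fine-scale roughness, independent of the shelf slope, so habitat
  # complexity is not slaved to habitat topography
  rough_amp <- pmax(smooth_noise(nyr, nxr, sigma = 4), 0)
  rough <- 0.8 * rough_amp * smooth_noise(nyr, nxr, sigma = 0.7)
  if (preset == "wet") {
    z <- -14 * (doff / 1400)^0.9 - 0.3 + 0.5 * nb + rough +
      1.2 * sin(2 * pi * col(nb) / 10) * pmin(doff / 600, 1) * 0.4
    z <- pmin(pmax(z, -16), -0.2)
    wave <- 21697 * (1 + 0.19 * nw) * (1 + 0.25 * (doff / 1500 - 0.5))
  } else {
    z <- -22 * (doff / 1100)^1.1 - 0.3 + 0.5 * nb + 0.8 * nb2 + rough
    z <- pmin(pmax(z, -24), -0.2)
    wave <- 2756 * (1 + 0.067 * nw)
  }
  z[!ocean] <- NA_real_
  wv <- pmax(wave, 1); wv[!ocean] <- NA_real_
  bathymetry <- raster_grid(z, ar, c(0, ylo), units = "m")
  wave_power <- raster_grid(wv, ar, c(0, ylo), units = "kW.m-1")

  # ---- recharge zones -----------------------------------------------------
  bbox <- function(x1, x2, y1, y2)
    cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
  zone <- function(ring, cn, cp, name) list(
    geometry = list(type = "Polygon", coords = ring),
    attributes = list(name = name, conc_n = cn, conc_p = cp))
  if (preset == "wet") {
    recharge_zones <- feature_set(list(
      zone(bbox(-a, W + a, -a, H + a), 0.50, 0.20, "uniform")))
  } else {
    ysplit <- y0 + amp + 0.35 * (H - y0)    # lowland / upland divide
    recharge_zones <- feature_set(list(
      zone(bbox(-a, W / 2, ysplit, H + a), 2.70, 0.20, "west_upland"),
      zone(bbox(-a, W / 2, -a, ysplit), 0.25, 0.10, "west_lowland"),
      zone(bbox(W / 2, W + a, ysplit, H + a), 1.20, 0.15, "east_upland"),
      zone(bbox(W / 2, W + a, -a, ysplit), 0.25, 0.10, "east_lowland")))
  }

  # ---- anthropogenic sources in the coastal strip -------------------------
  inland_extent <- if (preset == "wet") 1000 else 3500
  strip_depth <- min(inland_extent, 0.35 * (H - y0 - amp))
  strip_cells <- which(land & u > 0 &
                         outer(yc, ys, `-`) <= strip_depth, arr.ind = TRUE)
  cell_pt <- function(rc) c((rc[2] - 0.5) * a, (rc[1] - 0.5) * a)
  # houses aggregate into small coastal communities: cells are drawn without
  # replacement, weighted by alongshore Gaussian kernels around a few centers
  centers <- sort(stats::runif(if (preset == "wet") 3 else 4, 0.1 * W, 0.9 * W))
  comm_w <- rowSums(vapply(centers, function(c0)
    exp(-((strip_cells[, 2] - 0.5) * a - c0)^2 / (2 * 220^2)),
    numeric(nrow(strip_cells)))) + 1e-6
  pick <- function(n, clustered = TRUE) {
    pr <- if (clustered) comm_w else NULL
    if (n <= nrow(strip_cells))
      strip_cells[sample(nrow(strip_cells), n, prob = pr), , drop = FALSE]
    else strip_cells[sample(nrow(strip_cells), n, replace = TRUE, prob = pr), , drop = FALSE]
  }
  pt_feature <- function(rc, cls) list(
    geometry = list(type = "Point", coords = cell_pt(rc)),
    attributes = list(class = cls, units = 1))
  sq_feature <- function(center, area_m2, cls) {
    s <- sqrt(area_m2) / 2
    list(geometry = list(type = "Polygon",
                         coords = bbox(center[1] - s, center[1] + s,
                                       center[2] - s, center[2] + s)),
         attributes = list(class = cls))
  }
  feats <- list()
  if (preset == "wet") {
    cp <- pick(99); sp <- pick(37); lw <- pick(3)
    for (k in seq_len(99)) feats <- c(feats, list(pt_feature(cp[k, ], "cesspool")))
    for (k in seq_len(37)) feats <- c(feats, list(pt_feature(sp[k, ], "septic")))
    for (k in seq_len(3))                       # 3 lawns x 2 ha = 6 ha
      feats <- c(feats, list(sq_feature(cell_pt(lw[k, ]), 2e4, "lawn")))
    injection_volume <- 0
    stream_area_fraction <- 1
  } else {
    cp <- pick(193); lw <- pick(3); gf <- pick(1); iw <- pick(1)
    for (k in seq_len(193)) feats <- c(feats, list(pt_feature(cp[k, ], "cesspool")))
    for (k in seq_len(3))                       # lawns, 4.5 ha total
      feats <- c(feats, list(sq_feature(cell_pt(lw[k, ]), 1.5e4, "lawn")))
    feats <- c(feats, list(sq_feature(cell_pt(gf[1, ]), 19e4, "golf")))
    feats <- c(feats, list(pt_feature(iw[1, ], "injection_well")))
    injection_volume <- 160600
    stream_area_fraction <- 0
  }
  sources <- feature_set(feats)

  structure(list(
    preset = preset, size = size, seed = seed,
    rainfall = rainfall, actual_et = actual_et, transmissivity = transmissivity,
    bathymetry = bathymetry, wave_power = wave_power,
    shoreline = shoreline, recharge_zones = recharge_zones, sources = sources,
    params = list(dr_fraction = drf, inland_extent = inland_extent,
                  tube_spacing = 200, injection_volume = injection_volume,
                  stream_area_fraction = stream_area_fraction,
                  max_shore_distance = 1000),
    truth = truth_spec(preset, seed)),
    class = "site_bundle")
}

#' @export
print.site_bundle <- function(x, ...) {
  cat("<site_bundle>", x$preset, "preset,", x$size, "x", x$size,
      "land cells @ 50 m, seed", x$seed, "\n")
  cat("  sources:", length(x$sources), "features;",
      length(x$recharge_zones), "recharge zone(s)\n")
  invisible(x)
}

# seeded smooth random field (unit-ish variance) by Gaussian smoothing of
# white noise; uses the current RNG stream
smooth_noise <- function(nr, nc, sigma = 3) {
  pad <- ceiling(3 * sigma)
  w <- stats::dnorm(-pad:pad, sd = sigma)
  m <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  m <- apply(m, 2, function(cl) stats::filter(cl, w, sides = 2))
  m <- t(apply(m, 1, function(rw) stats::filter(rw, w, sides = 2)))
  core <- m[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  core / stats::sd(core, na.rm = TRUE)
}

# per-indicator generative response spec: transformed-scale linear predictor
# over z-scored drivers (first term tanh-saturating), benthic feeding fish
truth_spec <- function(preset, seed) {
  term <- function(driver, coef, shape = "linear") list(driver = driver, coef = coef, shape = shape)
  if (preset == "wet") {
    benthic <- list(
      cca = list(intercept = 4.5, terms = list(
        term("wave_power", 0.9, "tanh"), term("freshwater", -0.8),
        term("dist_shore", 0.4))),
      coral = list(intercept = 3.0, terms = list(
        term("freshwater", -0.9, "tanh"), term("wave_power", -0.6),
        term("rugosity", 0.6))),
      turf = list(intercept = 6.5, terms = list(
        term("freshwater", 0.8, "tanh"), term("n_flux", 0.5))),
      macroalgae = list(intercept = 2.5, terms = list(
        term("n_flux", 0.9, "tanh"), term("dist_shore", -0.5))))
    fish <- list(
      browser = list(intercept = 1.2, terms = list(
        term("n_flux", -0.45, "tanh"), term("cca", 0.25, "benthic"))),
      grazer = list(intercept = 1.6, terms = list(
        term("turf", 0.4, "benthic"), term("rugosity", 0.3))),
      scraper = list(intercept = 1.3, terms = list(
        term("wave_power", 0.5, "tanh"), term("macroalgae", -0.3, "benthic"))),
      piscivore = list(intercept = 0.9, terms = list(
        term("n_flux", -0.4, "tanh"), term("dist_shore", 0.3))))
  } else {
    benthic <- list(
      cca = list(intercept = 3.0, terms = list(
        term("n_flux", -0.9, "tanh"), term("dist_shore", -0.4),
        term("slope_60", 0.4))),
      coral = list(intercept = 4.5, terms = list(
        term("slope_60", 0.8, "tanh"), term("rugosity", 0.6),
        term("freshwater", -0.4))),
      turf = list(intercept = 6.0, terms = list(
        term("p_flux", 0.9, "tanh"), term("slope_60", -0.4))),
      macroalgae = list(intercept = 2.0, terms = list(
        term("n_flux", 0.6, "tanh"), term("dist_shore", -0.5))))
    fish <- list(
      browser = list(intercept = 1.2, terms = list(
        term("p_flux", -0.5, "tanh"), term("turf", 0.3, "benthic"))),
      grazer = list(intercept = 1.5, terms = list(
        term("turf", 0.4, "benthic"), term("rugosity", 0.3))),
      scraper = list(intercept = 1.4, terms = list(
        term("wave_power", 0.4, "tanh"), term("coral", 0.3, "benthic"))),
      piscivore = list(intercept = 0.8, terms = list(
        term("dist_shore", 0.4, "tanh"), term("depth", -0.3))))
  }
  list(benthic = benthic, fish = fish, seed = seed,
       benthic_clip = c(0, 10), fish_clip = c(0, 4))
}

#' Generate synthetic reef surveys with known ground truth
#'
#' Samples `n` reef cells (jittered within the cell), evaluates each
#' indicator's generative response - a smooth function of 2-4 named drivers
#' on the transformed scale (square root for benthic cover, fourth root for
#' fish biomass), with fish responses also consuming the benthic truth -
#' adds Gaussian noise on the transformed scale, clips, and back-transforms.
#' At `noise_frac = 0` the returned indicators equal the truth functions
#' exactly at the sampled locations.
#'
#' @param bundle a `site_bundle`.
#' @param stack a `driver_stack` computed for the bundle (must include the
#'   terrestrial plume layers).
#' @param n number of surveys (>= 30).
#' @param seed integer seed.
#' @param noise_frac noise standard deviation as a fraction of each
#'   indicator's transformed-scale signal SD (default 0.25).
#' @return data.frame `x`, `y`, four benthic % covers, four fish biomasses;
#'   attributes `truth` (spec + standardization + active drivers),
#'   `truth_transformed` (noiseless transformed-scale values),
#'   `drivers` (sampled predictor table).
#' @export
generate_surveys <- function(bundle, stack, n, seed = 1, noise_frac = 0.25) {
  if (n < 30) stop("need n >= 30 surveys")
  ts <- bundle$truth
  g <- stack[[1]]
  valid <- Reduce(`&`, lapply(stack, function(r) !is.na(r$values)))
  cells <- which(valid, arr.ind = TRUE)
  if (n > nrow(cells)) stop("n exceeds the ", nrow(cells), " available reef cells")
  set.seed(seed)
  take <- cells[sample(nrow(cells), n), , drop = FALSE]
  a <- g$cell_size
  pts <- data.frame(
    x = g$origin[1] + (take[, 2] - 0.5 + stats::runif(n, -0.3, 0.3)) * a,
    y = g$origin[2] + (take[, 1] - 0.5 + stats::runif(n, -0.3, 0.3)) * a)
  X <- sample_at_points(stack, pts)
  # plume drivers span orders of magnitude; responses are defined on their
  # log scale so the gradients are ecologically smooth across the domain
  log_drivers <- c("freshwater", "n_flux", "p_flux")
  Xz <- X
  for (nm in intersect(log_drivers, names(Xz))) Xz[[nm]] <- log1p(Xz[[nm]])
  mu <- vapply(Xz, mean, 0); sdv <- vapply(Xz, stats::sd, 0)
  sdv[sdv == 0] <- 1
  zed <- function(nm) (Xz[[nm]] - mu[nm]) / sdv[nm]
  eval_terms <- function(spec, benthic_t) {
    v <- rep(spec$intercept, n)
    for (tm in spec$terms) {
      zt <- if (tm$shape == "benthic") benthic_t[[tm$driver]] - 3  # centered
            else zed(tm$driver)
      v <- v + tm$coef * (if (tm$shape == "tanh") tanh(zt) else zt)
    }
    v
  }
  benthic_t <- lapply(ts$benthic, eval_terms, benthic_t = NULL)
  fish_t <- lapply(ts$fish, eval_terms, benthic_t = benthic_t)
  truth_t <- c(benthic_t, fish_t)
  noisy <- function(tv, clip) {
    s <- noise_frac * stats::sd(tv)
    pmin(pmax(tv + stats::rnorm(n, 0, s), clip[1]), clip[2])
  }
  out <- pts
  for (nm in names(ts$benthic))
    out[[nm]] <- inverse_transform(noisy(truth_t[[nm]], ts$benthic_clip),
                                   "sqrt", upper = 100)
  for (nm in names(ts$fish))
    out[[nm]] <- inverse_transform(noisy(truth_t[[nm]], ts$fish_clip),
                                   "fourth_root")
  active <- lapply(c(ts$benthic, ts$fish), function(s)
    vapply(s$terms, function(tm) tm$driver, ""))
  attr(out, "truth") <- list(spec = ts, mu = mu, sd = sdv, active = active,
                             noise_frac = noise_frac, seed = seed)
  attr(out, "truth_transformed") <- as.data.frame(truth_t)
  attr(out, "drivers") <- X
  out
}

#' Write a site bundle to a directory in the standard formats
#'
#' Rasters as ASCII grids, vectors as GeoJSON, preset parameters as YAML.
#'
#' @param bundle a `site_bundle`.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_site <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("rainfall", "actual_et", "transmissivity", "bathymetry",
               "wave_power"))
    write_ascii_grid(bundle[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (nm in c("shoreline", "recharge_zones", "sources"))
    write_geojson(bundle[[nm]], file.path(dir, paste0(nm, ".geojson")))
  yaml::write_yaml(c(list(preset = bundle$preset, size = bundle$size,
                          seed = bundle$seed), bundle$params),
                   file.path(dir, "site.yaml"))
  invisible(dir)
}

#' Effluent recharge raster from OSDS sources
#'
#' Converts cesspool and septic point features into the per-cell effluent
#' recharge depth (m yr-1) entering the recharge balance: units x 435 m3
#' divided by the cell area.
#'
#' @param sources a [feature_set()].
#' @param grid land template [raster_grid()].
#' @param volume_per_unit wastewater volume per residence (m3 yr-1).
#' @return [raster_grid()] (m yr-1), zero where no OSDS.
#' @export
osds_recharge <- function(sources, grid, volume_per_unit = 435) {
  m <- matrix(0, nrow(grid$values), ncol(grid$values))
  for (f in sources$features) {
    if (f$geometry$type != "Point") next
    if (!f$attributes$class %in% c("cesspool", "septic")) next
    rc <- cell_of(grid, matrix(f$geometry$coords, 1))
    if (is.na(rc[1])) next
    units <- f$attributes$units %||% 1
    m[rc[1], rc[2]] <- m[rc[1], rc[2]] + units * volume_per_unit / grid$cell_size^2
  }
  m[is.na(grid$values)] <- NA_real_
  grid_with(grid, m, units = "m.yr-1")
}
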