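#' Nutrient flux from a concentration and an annual water volume
#'
#' `flux (kg yr-1) = conc (mg L-1) x volume (m3 yr-1) x 1e-3`, since
#' 1 mg L-1 = 1 g m-3. E.g. a cesspool leaching 435 m3 yr-1 of effluent at
#' 87 mg L-1 N yields 37.845 kg N yr-1.
#'
#' @param conc concentration, mg L-1 (>= 0).
#' @param volume annual water volume, m3 yr-1 (>= 0).
#' @return flux in kg yr-1.
#' @export
flux_from_concentration <- function(conc, volume) {
  if (any(conc < 0, na.rm = TRUE) || any(volume < 0, na.rm = TRUE))
    stop("conc and volume must be >= 0")
  conc * volume * 1e-3
}

#' Nutrient source class table
#'
#' Default per-class loading parameters for the anthropogenic source classes:
#' effluent concentrations, per-unit wastewater volumes (each residence is
#' assumed three bedrooms at 1.5 persons per bedroom, generating 435 m3 yr-1),
#' injection-well permitted discharge, lawn irrigation recharge, golf-course
#' fertilization, and the authoritative per-unit / per-hectare N and P flux
#' values the pipeline consumes. For the diffuse classes the flux columns are
#' the literature loading rates rather than the conc x volume product (soil
#' sorption and background contributions enter those rates); `delivery_p`
#' exposes a dimensionless P delivery factor (1 = no sorption, the wastewater
#' assumption).
#'
#' @return data.frame with one row per class (`cesspool`, `septic`,
#'   `injection_well`, `lawn`, `golf`), columns `basis` (`per_unit` or
#'   `per_area`), `conc_n`, `conc_p` (mg L-1), `volume` (m3 yr-1 per unit),
#'   `recharge_rate` (m3 ha-1 d-1, diffuse classes), `flux_n`, `flux_p`
#'   (kg yr-1 per unit or kg ha-1 yr-1), `delivery_p`.
#' @export
source_class_table <- function() {
  data.frame(
    name = c("cesspool", "septic", "injection_well", "lawn", "golf"),
    basis = c("per_unit", "per_unit", "per_unit", "per_area", "per_area"),
    conc_n = c(87, 34.2, 5.25, 0.20, 7.59),
    conc_p = c(19, 1.2, 6.8, 0.01, 0.54),
    volume = c(435, 435, 160600, NA, NA),
    recharge_rate = c(NA, NA, NA, 50, NA),
    flux_n = c(38, 14.9, 843, 4.5, 49),
    flux_p = c(8.3, 5.2, 1300, 0.2, 13.5),
    delivery_p = 1,
    stringsAsFactors = FALSE)
}

#' Background nutrient flux from recharge-zone concentrations
#'
#' Each recharge zone polygon carries representative background N and P
#' concentrations; per cell, flux = zone concentration x recharge volume of
#' the cell (recharge depth x cell area), giving kg yr-1 per cell. Zones must
#' cover every active recharge cell.
#'
#' @param zones a [feature_set()] of polygons with `conc_n`, `conc_p`
#'   attributes (mg L-1).
#' @param recharge recharge [raster_grid()] (m yr-1).
#' @return list of two rasters `n` and `p` (kg yr-1 per cell).
#' @export
background_flux <- function(zones, recharge) {
  a <- recharge$cell_size
  xy <- grid_xy(recharge)
  act <- !is.na(as.vector(recharge$values))
  zone_id <- rep(NA_integer_, nrow(xy))
  for (k in seq_along(zones$features)) {
    f <- zones$features[[k]]
    if (f$geometry$type != "Polygon") stop("recharge zones must be polygons")
    inside <- mgcv::in.out(f$geometry$coords, xy) > 0
    zone_id[is.na(zone_id) & inside] <- k
  }
  if (any(act & is.na(zone_id)))
    stop(sum(act & is.na(zone_id)), " recharge cell(s) fall in no zone")
  cn <- vapply(zones$features, function(f) as.numeric(f$attributes$conc_n), 0)
  cp <- vapply(zones$features, function(f) as.numeric(f$attributes$conc_p), 0)
  if (any(cn < 0) || any(cp < 0)) stop("zone concentrations must be >= 0")
  vol <- as.vector(recharge$values) * a^2  # m3/yr per cell
  nfx <- flux_from_concentration(cn[zone_id], vol)
  pfx <- flux_from_concentration(cp[zone_id], vol)
  dims <- dim(recharge$values)
  list(n = grid_with(recharge, matrix(nfx, dims[1], dims[2]), units = "kg.yr-1"),
       p = grid_with(recharge, matrix(pfx, dims[1], dims[2]), units = "kg.yr-1"))
}

#' Rasterize anthropogenic nutrient sources
#'
#' Point features (class `cesspool`, `septic`, `injection_well`) contribute
#' their per-unit flux to the cell containing them; polygon features (`lawn`,
#' `golf`) contribute per-hectare flux weighted by the polygon area falling in
#' each cell (exact rectangle clipping), so the domain total is independent of
#' cell size. Features outside the grid are skipped with a log message.
#'
#' @param sources a [feature_set()]; each feature needs a `class` attribute
#'   naming a row of `classes`.
#' @param grid template [raster_grid()] for the output.
#' @param classes class table, see [source_class_table()].
#' @return list of rasters `n` and `p` (kg yr-1 per cell) plus `skipped`
#'   (count of out-of-domain features).
#' @export
rasterize_sources <- function(sources, grid, classes = source_class_table()) {
  dims <- dim(grid$values)
  nfx <- matrix(0, dims[1], dims[2])
  pfx <- matrix(0, dims[1], dims[2])
  skipped <- 0L
  for (f in sources$features) {
    cls <- f$attributes$class
    k <- match(cls, classes$name)
    if (is.na(k)) stop("unknown source class: ", cls)
    if (f$geometry$type == "Point") {
      if (classes$basis[k] != "per_unit")
        stop("class ", cls, " is per-area but the feature is a point")
      rc <- cell_of(grid, matrix(f$geometry$coords, 1))
      if (is.na(rc[1])) { skipped <- skipped + 1L; next }
      n_units <- f$attributes$units %||% 1
      nfx[rc[1], rc[2]] <- nfx[rc[1], rc[2]] + n_units * classes$flux_n[k]
      pfx[rc[1], rc[2]] <- pfx[rc[1], rc[2]] +
        n_units * classes$flux_p[k] * classes$delivery_p[k]
    } else if (f$geometry$type == "Polygon") {
      if (classes$basis[k] != "per_area")
        stop("class ", cls, " is per-unit but the feature is a polygon")
      w <- polygon_cell_areas(f$geometry$coords, grid)  # m2 per cell
      if (sum(w) == 0) { skipped <- skipped + 1L; next }
      ha <- w / 1e4
      nfx <- nfx + ha * classes$flux_n[k]
      pfx <- pfx + ha * classes$flux_p[k] * classes$delivery_p[k]
    } else stop("unsupported source geometry: ", f$geometry$type)
  }
  if (skipped) message("rasterize_sources: skipped ", skipped,
                       " feature(s) outside the grid")
  list(n = grid_with(grid, nfx, units = "kg.yr-1"),
       p = grid_with(grid, pfx, units = "kg.yr-1"),
       skipped = skipped)
}

# area of polygon ring clipped to each grid cell (Sutherland-Hodgman against
# the four half-planes of the cell rectangle); returns a matrix of m2
polygon_cell_areas <- function(ring, grid) {
  dims <- dim(grid$values)
  a <- grid$cell_size
  out <- matrix(0, dims[1], dims[2])
  # restrict to candidate cells overlapping the ring bbox
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  jr <- floor((range(ring[, 1]) - x0) / a) + c(1, 1)
  ir <- floor((range(ring[, 2]) - y0) / a) + c(1, 1)
  js <- max(1, jr[1]):min(dims[2], jr[2])
  is <- max(1, ir[1]):min(dims[1], ir[2])
  if (!length(js) || !length(is)) return(out)
  poly <- ring[-nrow(ring), , drop = FALSE]  # open ring for clipping
  for (i in is) for (j in js) {
    xmin <- x0 + (j - 1) * a; xmax <- xmin + a
    ymin <- y0 + (i - 1) * a; ymax <- ymin + a
    p <- clip_halfplane(poly, function(pt) pt[1] >= xmin,
                        function(p1, p2) intersect_x(p1, p2, xmin))
    if (nrow(p) > 2) p <- clip_halfplane(p, function(pt) pt[1] <= xmax,
                                         function(p1, p2) intersect_x(p1, p2, xmax))
    if (nrow(p) > 2) p <- clip_halfplane(p, function(pt) pt[2] >= ymin,
                                         function(p1, p2) intersect_y(p1, p2, ymin))
    if (nrow(p) > 2) p <- clip_halfplane(p, function(pt) pt[2] <= ymax,
                                         function(p1, p2) intersect_y(p1, p2, ymax))
    if (nrow(p) > 2) out[i, j] <- polygon_area(rbind(p, p[1, ]))
  }
  out
}

clip_halfplane <- function(poly, inside, intersect) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  keep <- matrix(0, 0, 2)
  for (k in seq_len(n)) {
    cur <- poly[k, ]; prv <- poly[if (k == 1) n else k - 1, ]
    ci <- inside(cur); pi <- inside(prv)
    if (ci) {
      if (!pi) keep <- rbind(keep, intersect(prv, cur))
      keep <- rbind(keep, cur)
    } else if (pi) {
      keep <- rbind(keep, intersect(prv, cur))
    }
  }
  keep
}

intersect_x <- function(p1, p2, x) {
  t <- (x - p1[1]) / (p2[1] - p1[1])
  c(x, p1[2] + t * (p2[2] - p1[2]))
}
intersect_y <- function(p1, p2, y) {
  t <- (y - p1[2]) / (p2[2] - p1[2])
  c(p1[1] + t * (p2[1] - p1[1]), y)
}
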