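# Shift a matrix by (di, dj) cells, padding by edge replication so 3x3
# windows are defined at borders (border metrics are one-sided there).
shift_pad <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, cj, drop = FALSE]
}

# 3x3 quadratic fit z = A x^2 + B y^2 + C xy + D x + E y + F by least squares;
# returns coefficient maps. NA neighbors are replaced by the center value.
quad_fit <- function(bathy) {
  z <- bathy$values
  a <- bathy$cell_size
  offs <- expand.grid(dj = -1:1, di = -1:1)
  X <- cbind((offs$dj * a)^2, (offs$di * a)^2, offs$dj * a * offs$di * a,
             offs$dj * a, offs$di * a, 1)
  P <- solve(crossprod(X), t(X))  # 6 x 9 projector
  co <- vector("list", 6)
  for (k in 1:6) co[[k]] <- matrix(0, nrow(z), ncol(z))
  for (s in seq_len(nrow(offs))) {
    zs <- shift_pad(z, offs$di[s], offs$dj[s])
    zs[is.na(zs)] <- z[is.na(zs)]
    for (k in 1:6) co[[k]] <- co[[k]] + P[k, s] * zs
  }
  names(co) <- c("A", "B", "C", "D", "E", "F")
  co$valid <- !is.na(z)
  co
}

#' Seafloor slope and aspect
#'
#' 3x3 quadratic-fit gradient. Slope is `atan(|grad z|)` in degrees; aspect is
#' the downslope compass direction (0 = north, 90 = east) in `[0, 360)`,
#' nodata where the surface is locally flat.
#'
#' @param bathy bathymetry [raster_grid()] (m, negative below sea level).
#' @param flat_tol gradient magnitude below which aspect is undefined.
#' @return list of rasters `slope` (degrees) and `aspect` (degrees).
#' @export
slope_aspect <- function(bathy, flat_tol = 1e-9) {
  co <- quad_fit(bathy)
  p <- co$D; q <- co$E
  g <- sqrt(p^2 + q^2)
  slope <- atan(g) * 180 / pi
  asp <- (atan2(-p, -q) * 180 / pi) %% 360
  asp[g < flat_tol] <- NA_real_
  slope[!co$valid] <- NA_real_; asp[!co$valid] <- NA_real_
  list(slope = grid_with(bathy, slope, units = "degrees"),
       aspect = grid_with(bathy, asp, units = "degrees"))
}

#' Bathymetric position index
#'
#' Center depth minus the mean depth over a circular neighborhood of the
#' given radius (center excluded): positive on ridges and pinnacles, negative
#' in depressions, zero on planes.
#'
#' @param bathy bathymetry [raster_grid()].
#' @param radius neighborhood radius in meters (>= cell size).
#' @return BPI [raster_grid()] (m).
#' @export
bpi <- function(bathy, radius) {
  a <- bathy$cell_size
  if (radius < a) stop("radius must be >= cell_size")
  z <- bathy$values
  k <- floor(radius / a)
  s <- matrix(0, nrow(z), ncol(z)); n <- matrix(0, nrow(z), ncol(z))
  for (di in -k:k) for (dj in -k:k) {
    if (di == 0 && dj == 0) next
    if (sqrt(di^2 + dj^2) * a > radius) next
    zs <- shift_pad(z, di, dj)
    ok <- !is.na(zs)
    s[ok] <- s[ok] + zs[ok]
    n <- n + ok
  }
  out <- z - s / n
  out[n == 0] <- NA_real_
  grid_with(bathy, out, units = "m")
}

#' Planar and profile curvature
#'
#' From a 3x3 quadratic surface fit: profile curvature is the second
#' directional derivative along the gradient (flow accelerates or
#' decelerates), planar curvature the one across it (flow converges or
#' diverges); both in radians m-1, and both zero where the gradient is
#' degenerate.
#'
#' @param bathy bathymetry [raster_grid()].
#' @param flat_tol gradient magnitude treated as degenerate.
#' @return list of rasters `planar` and `profile`.
#' @export
curvatures <- function(bathy, flat_tol = 1e-9) {
  co <- quad_fit(bathy)
  p <- co$D; q <- co$E
  g2 <- p^2 + q^2
  # Hessian [[2A, C], [C, 2B]]
  prof <- (2 * co$A * p^2 + 2 * co$B * q^2 + 2 * co$C * p * q) / g2
  plan <- (2 * co$A * q^2 + 2 * co$B * p^2 - 2 * co$C * p * q) / g2
  deg <- g2 < flat_tol^2
  prof[deg] <- 0; plan[deg] <- 0
  prof[!co$valid] <- NA_real_; plan[!co$valid] <- NA_real_
  list(planar = grid_with(bathy, plan, units = "radians.m-1"),
       profile = grid_with(bathy, prof, units = "radians.m-1"))
}

#' Surface rugosity
#'
#' Ratio of true surface area to planimetric area per 3x3 window, computed
#' from the fan of eight triangles joining the center to its ring of
#' neighbors. Exactly 1 on a flat surface and `1/cos(slope)` on a tilted
#' plane; unbounded above with increasing roughness.
#'
#' @param bathy bathymetry [raster_grid()].
#' @return rugosity [raster_grid()] (unitless, >= 1).
#' @export
rugosity <- function(bathy) {
  z <- bathy$values
  a <- bathy$cell_size
  ring <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  zs <- lapply(ring, function(s) {
    m <- shift_pad(z, s[1], s[2]); m[is.na(m)] <- z[is.na(m)]; m
  })
  area3d <- matrix(0, nrow(z), ncol(z))
  plan <- 0
  for (k in seq_along(ring)) {
    k2 <- if (k == length(ring)) 1L else k + 1L
    v1 <- c(ring[[k]][2], ring[[k]][1]) * a   # (x, y) of neighbor 1
    v2 <- c(ring[[k2]][2], ring[[k2]][1]) * a
    dz1 <- zs[[k]] - z
    dz2 <- zs[[k2]] - z
    # |cross((v1, dz1), (v2, dz2))| / 2
    cx <- v1[2] * dz2 - dz1 * v2[2]
    cy <- dz1 * v2[1] - v1[1] * dz2
    cz <- v1[1] * v2[2] - v1[2] * v2[1]
    area3d <- area3d + sqrt(cx^2 + cy^2 + cz^2) / 2
    plan <- plan + abs(cz) / 2
  }
  out <- area3d / plan
  out[is.na(z)] <- NA_real_
  grid_with(bathy, out, units = "unitless")
}

#' Circular statistics of aspect over a neighborhood
#'
#' Circular mean direction via the mean resultant vector over a circular
#' neighborhood (center included): northness = cos(mean), eastness =
#' sin(mean), and circular standard deviation `sqrt(-2 ln Rbar)` (radians).
#'
#' @param aspect aspect [raster_grid()] in degrees compass `[0, 360)`.
#' @param radius neighborhood radius in meters.
#' @return list of rasters `northness`, `eastness`, `aspect_sd`.
#' @export
circular_stats <- function(aspect, radius) {
  a <- aspect$cell_size
  th <- aspect$values * pi / 180
  k <- floor(radius / a)
  S <- matrix(0, nrow(th), ncol(th)); C <- matrix(0, nrow(th), ncol(th))
  n <- matrix(0, nrow(th), ncol(th))
  for (di in -k:k) for (dj in -k:k) {
    if (sqrt(di^2 + dj^2) * a > radius) next
    ts <- shift_pad(th, di, dj)
    ok <- !is.na(ts)
    S[ok] <- S[ok] + sin(ts[ok])
    C[ok] <- C[ok] + cos(ts[ok])
    n <- n + ok
  }
  rbar <- sqrt(S^2 + C^2) / n
  mu <- atan2(S, C)
  northness <- cos(mu); eastness <- sin(mu)
  sdv <- sqrt(pmax(-2 * log(pmin(rbar, 1)), 0))
  bad <- n == 0
  northness[bad] <- NA_real_; eastness[bad] <- NA_real_; sdv[bad] <- NA_real_
  list(northness = grid_with(aspect, northness, units = "unitless"),
       eastness = grid_with(aspect, eastness, units = "unitless"),
       aspect_sd = grid_with(aspect, sdv, units = "radians"))
}

#' Euclidean distance to the shoreline
#'
#' Per cell center, the minimum distance to any shoreline segment (not just
#' its vertices).
#'
#' @param shoreline a [feature_set()] containing LineString feature(s), or an
#'   n x 2 coordinate matrix.
#' @param grid template [raster_grid()].
#' @return distance [raster_grid()] (m), defined on all cells.
#' @export
distance_to_shore <- function(shoreline, grid) {
  coords <- shoreline_coords(shoreline)
  if (nrow(coords) < 2) stop("shoreline needs >= 2 vertices")
  xy <- grid_xy(grid)
  d2 <- rep(Inf, nrow(xy))
  for (s in seq_len(nrow(coords) - 1)) {
    p1 <- coords[s, ]; p2 <- coords[s + 1, ]
    v <- p2 - p1
    L2 <- sum(v^2)
    if (L2 == 0) {
      dd <- (xy[, 1] - p1[1])^2 + (xy[, 2] - p1[2])^2
    } else {
      t <- pmin(pmax(((xy[, 1] - p1[1]) * v[1] + (xy[, 2] - p1[2]) * v[2]) / L2, 0), 1)
      dd <- (xy[, 1] - p1[1] - t * v[1])^2 + (xy[, 2] - p1[2] - t * v[2])^2
    }
    d2 <- pmin(d2, dd)
  }
  grid_with(grid, matrix(sqrt(d2), nrow(grid$values), ncol(grid$values)),
            units = "m")
}

shoreline_coords <- function(shoreline) {
  if (is.matrix(shoreline)) return(shoreline)
  ls <- Filter(function(f) f$geometry$type == "LineString", shoreline$features)
  if (!length(ls)) stop("no LineString in shoreline feature set")
  do.call(rbind, lapply(ls, function(f) f$geometry$coords))
}

#' Aggregate a raster to a coarser resolution by block mean
#'
#' @param grid a [raster_grid()].
#' @param factor integer block size (cells per side).
#' @return coarser [raster_grid()]; blocks that are all nodata stay nodata.
#' @export
aggregate_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  z <- grid$values
  nr <- floor(nrow(z) / factor); nc <- floor(ncol(z) / factor)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- z[((i - 1) * factor + 1):(i * factor), ((j - 1) * factor + 1):(j * factor)]
    if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
  }
  raster_grid(out, grid$cell_size * factor, grid$origin, grid$nodata, grid$units)
}

#' Assemble a co-registered driver stack
#'
#' Derives the full marine driver layer set from bathymetry, wave power and
#' the shoreline at the reef resolution: wave power, depth, distance to
#' shore, BPI and slope at two neighborhood radii, planar/profile curvature,
#' rugosity, and aspect circular statistics. Terrestrial plume layers
#' (`freshwater`, `n_flux`, `p_flux`) are appended when supplied.
#'
#' @param bathy bathymetry [raster_grid()] at reef resolution (nodata on land).
#' @param wave_power wave power [raster_grid()] (kW m-1), co-registered.
#' @param shoreline shoreline [feature_set()] or coordinate matrix.
#' @param plumes optional named list of rasters from [stack_plumes()].
#' @param radii two neighborhood radii (m) for BPI/slope, default c(60, 240).
#' @return a named list of co-registered rasters, class `driver_stack`.
#' @export
build_driver_stack <- function(bathy, wave_power, shoreline, plumes = NULL,
                               radii = c(60, 240)) {
  check_registration(bathy, wave_power)
  sa <- slope_aspect(bathy)
  cv <- curvatures(bathy)
  cs <- circular_stats(sa$aspect, radii[2])
  slope2 <- focal_mean(sa$slope, radii[2])  # slope at the coarse radius
  st <- list(
    wave_power = wave_power,
    depth = bathy,
    dist_shore = mask_like(distance_to_shore(shoreline, bathy), bathy),
    bpi_60 = bpi(bathy, radii[1]),
    bpi_240 = bpi(bathy, radii[2]),
    slope_60 = sa$slope,
    slope_240 = slope2,
    plan_curv = cv$planar,
    prof_curv = cv$profile,
    rugosity = rugosity(bathy),
    northness = cs$northness,
    eastness = cs$eastness,
    aspect_sd = cs$aspect_sd)
  if (!is.null(plumes)) st <- c(st, plumes[c("freshwater", "n_flux", "p_flux")])
  for (g in st) check_registration(bathy, g)
  structure(st, class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat("<driver_stack>", length(x), "layers:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# mean over a circular neighborhood, NA-aware
focal_mean <- function(grid, radius) {
  a <- grid$cell_size
  z <- grid$values
  k <- floor(radius / a)
  s <- matrix(0, nrow(z), ncol(z)); n <- matrix(0, nrow(z), ncol(z))
  for (di in -k:k) for (dj in -k:k) {
    if (sqrt(di^2 + dj^2) * a > radius) next
    zs <- shift_pad(z, di, dj)
    ok <- !is.na(zs)
    s[ok] <- s[ok] + zs[ok]
    n <- n + ok
  }
  out <- s / n
  out[n == 0 | is.na(z)] <- NA_real_
  grid_with(grid, out, units = grid$units)
}

mask_like <- function(grid, template) {
  v <- grid$values
  v[is.na(template$values)] <- NA_real_
  grid_with(grid, v)
}
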