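#' Composite diffusion cost surface
#'
#' Combines the three marine drivers governing plume diffusion - water depth,
#' distance from shore and wave power - each min-max normalized to \[0, 1\]
#' over the valid reef cells, into a weighted sum (weights sum to 1, default
#' equal thirds). A constant driver is dropped with a warning and the
#' remaining weights renormalized. Land cells stay nodata.
#'
#' @param depth bathymetry [raster_grid()] (m, negative below sea level);
#'   impedance grows with water depth.
#' @param dist_shore distance-to-shore [raster_grid()] (m).
#' @param wave_power wave power [raster_grid()] (kW m-1).
#' @param weights numeric length 3, summing to 1.
#' @return cost [raster_grid()] in \[0, 1\] on valid reef cells.
#' @export
cost_surface <- function(depth, dist_shore, wave_power,
                         weights = rep(1 / 3, 3)) {
  check_registration(depth, dist_shore, wave_power)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  layers <- list(-depth$values, dist_shore$values, wave_power$values)
  valid <- !is.na(depth$values)
  norm <- list(); keep <- logical(3)
  for (k in 1:3) {
    v <- layers[[k]]
    rng <- range(v[valid], na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("cost_surface: driver ", k, " is constant; dropped")
      keep[k] <- FALSE
    } else {
      norm[[k]] <- (v - rng[1]) / diff(rng)
      keep[k] <- TRUE
    }
  }
  if (!any(keep)) stop("all cost drivers are constant")
  w <- weights[keep] / sum(weights[keep])
  out <- matrix(0, nrow(depth$values), ncol(depth$values))
  kk <- 1
  for (k in which(keep)) { out <- out + w[kk] * norm[[k]]; kk <- kk + 1 }
  out[!valid] <- NA_real_
  grid_with(depth, out, units = "unitless")
}

#' Least accumulative cost distance from a source cell
#'
#' Dijkstra shortest paths over the 8-neighbor graph of valid cells. The edge
#' weight between adjacent cells is the mean of their per-cell costs times the
#' center-to-center distance (diagonals x sqrt(2)); the source value is 0 and
#' values are non-decreasing along any least-cost path.
#'
#' @param cost cost [raster_grid()] (nodata cells are impassable).
#' @param source length-2 integer (row, col) of the source cell.
#' @return accumulated cost [raster_grid()]; unreachable cells nodata.
#' @export
accumulate_cost <- function(cost, source) {
  cm <- cost$values
  nr <- nrow(cm); nc <- ncol(cm)
  i0 <- source[1]; j0 <- source[2]
  if (is.na(cm[i0, j0])) stop("source cell is nodata")
  a <- cost$cell_size
  n <- nr * nc
  dist <- rep(Inf, n)
  done <- is.na(as.vector(cm))  # impassable cells never enter the queue
  s <- (j0 - 1L) * nr + i0
  dist[s] <- 0
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  step_len <- sqrt(offs[, 1]^2 + offs[, 2]^2) * a
  cv <- as.vector(cm)
  repeat {
    u <- which.min(replace(dist, done, Inf))
    if (!length(u) || is.infinite(dist[u]) || all(done | is.infinite(dist)))
      break
    if (done[u]) break
    done[u] <- TRUE
    iu <- ((u - 1L) %% nr) + 1L
    ju <- ((u - 1L) %/% nr) + 1L
    for (k in 1:8) {
      i2 <- iu + offs[k, 1]; j2 <- ju + offs[k, 2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      v <- (j2 - 1L) * nr + i2
      if (done[v]) next
      w <- (cv[u] + cv[v]) / 2 * step_len[k]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  out <- matrix(dist, nr, nc)
  out[is.infinite(out) | is.na(cm)] <- NA_real_
  grid_with(cost, out, units = "unitless")
}

#' Exponential plume decay of a pour-point loading
#'
#' Spreads a pour-point loading over the reef as
#' `W = L_p * exp(-c^2 / D_c)`, where `c` is the accumulated cost from the
#' pour point and `D_c` the cost threshold equivalent to the maximum plume
#' extent; cells farther than `max_shore_distance` from the shoreline receive
#' zero. With `conserve = TRUE` the field is rescaled so its cell sum equals
#' `L_p` (the loading is redistributed rather than used as a peak value).
#'
#' @param L_p pour-point loading (m3 yr-1 or kg yr-1, >= 0).
#' @param costdist accumulated-cost [raster_grid()] from [accumulate_cost()].
#' @param D_c cost threshold (> 0); see [calibrate_dc()].
#' @param dist_shore distance-to-shore [raster_grid()].
#' @param max_shore_distance plume cutoff from the shoreline (m).
#' @param conserve rescale so the plume sums to `L_p`.
#' @return plume [raster_grid()].
#' @export
diffuse <- function(L_p, costdist, D_c, dist_shore,
                    max_shore_distance = 1000, conserve = FALSE) {
  if (L_p < 0) stop("L_p must be >= 0")
  if (D_c <= 0) stop("D_c must be > 0")
  check_registration(costdist, dist_shore)
  w <- L_p * exp(-costdist$values^2 / D_c)
  w[dist_shore$values > max_shore_distance] <- 0
  if (conserve) {
    tot <- sum(w, na.rm = TRUE)
    if (tot > 0) w <- w * (L_p / tot)
  }
  grid_with(costdist, w, units = "per-cell loading")
}

#' Calibrate the cost threshold D_c for a site
#'
#' The decay threshold is defined as "the accumulated cost equivalent to the
#' maximum plume distance from shore". The convention adopted here: average,
#' over pour points, the least accumulated cost among reef cells lying at the
#' cutoff distance (within half a cell-diagonal band), and set
#' `D_c = mean(c*)^2 / 9`, so the kernel has decayed to `exp(-9)` (about
#' 0.01%) where the cutoff is reached.
#'
#' @param costdists list of accumulated-cost rasters, one per pour point.
#' @param dist_shore distance-to-shore [raster_grid()].
#' @param max_shore_distance cutoff (m).
#' @return `D_c` (> 0).
#' @export
calibrate_dc <- function(costdists, dist_shore, max_shore_distance = 1000) {
  a <- dist_shore$cell_size
  band <- abs(dist_shore$values - max_shore_distance) <= a * sqrt(2) / 2 + 1e-9
  if (!any(band, na.rm = TRUE))
    band <- dist_shore$values >= max(dist_shore$values[dist_shore$values <=
      max_shore_distance], na.rm = TRUE) - a
  cstar <- vapply(costdists, function(cd) {
    v <- cd$values[band & !is.na(cd$values)]
    if (!length(v)) NA_real_ else min(v)
  }, 0)
  cbar <- mean(cstar, na.rm = TRUE)
  if (!is.finite(cbar) || cbar <= 0) stop("cannot calibrate D_c: no reachable cutoff cells")
  cbar^2 / 9
}

#' Stack per-pour-point plumes into terrestrial driver rasters
#'
#' For each flow tube, accumulates the cost distance from its pour point and
#' diffuses the tube's water and nutrient fluxes; the per-quantity fields are
#' summed over tubes into the `freshwater` (m3 yr-1), `n_flux` and `p_flux`
#' (kg yr-1) terrestrial driver layers at the reef resolution.
#'
#' @param budget a `tube_budget` data.frame from [zone_budget()].
#' @param cost cost [raster_grid()] from [cost_surface()].
#' @param dist_shore distance-to-shore [raster_grid()].
#' @param D_c cost threshold; `NULL` calibrates per site via [calibrate_dc()].
#' @param max_shore_distance plume cutoff (m).
#' @param conserve mass-conserving mode (see [diffuse()]).
#' @return list: rasters `freshwater`, `n_flux`, `p_flux`; `per_tube` (list of
#'   per-tube N plume rasters, for attribution); `D_c`.
#' @export
stack_plumes <- function(budget, cost, dist_shore, D_c = NULL,
                         max_shore_distance = 1000, conserve = FALSE) {
  if (!nrow(budget)) stop("empty tube list")
  check_registration(cost, dist_shore)
  cds <- lapply(seq_len(nrow(budget)), function(k) {
    src <- nearest_valid_cell(cost, c(budget$x[k], budget$y[k]))
    accumulate_cost(cost, src)
  })
  if (is.null(D_c)) D_c <- calibrate_dc(cds, dist_shore, max_shore_distance)
  zero <- grid_with(cost, matrix(0, nrow(cost$values), ncol(cost$values)))
  acc <- list(freshwater = zero$values, n_flux = zero$values, p_flux = zero$values)
  per_tube <- vector("list", nrow(budget))
  for (k in seq_len(nrow(budget))) {
    fw <- diffuse(budget$water_flux[k], cds[[k]], D_c, dist_shore,
                  max_shore_distance, conserve)
    nf <- diffuse(budget$n_flux[k], cds[[k]], D_c, dist_shore,
                  max_shore_distance, conserve)
    pf <- diffuse(budget$p_flux[k], cds[[k]], D_c, dist_shore,
                  max_shore_distance, conserve)
    add <- function(acc, v) { v[is.na(v)] <- 0; acc + v }
    acc$freshwater <- add(acc$freshwater, fw$values)
    acc$n_flux <- add(acc$n_flux, nf$values)
    acc$p_flux <- add(acc$p_flux, pf$values)
    per_tube[[k]] <- nf
  }
  mask <- is.na(cost$values)
  for (nm in names(acc)) acc[[nm]][mask] <- NA_real_
  list(freshwater = grid_with(cost, acc$freshwater, units = "m3.yr-1"),
       n_flux = grid_with(cost, acc$n_flux, units = "kg.yr-1"),
       p_flux = grid_with(cost, acc$p_flux, units = "kg.yr-1"),
       per_tube = per_tube, D_c = D_c)
}

# nearest valid (non-nodata) cell of a grid to a point
nearest_valid_cell <- function(grid, p) {
  ok <- which(!is.na(grid$values), arr.ind = TRUE)
  if (!nrow(ok)) stop("grid has no valid cells")
  xs <- grid$origin[1] + (ok[, 2] - 0.5) * grid$cell_size
  ys <- grid$origin[2] + (ok[, 1] - 0.5) * grid$cell_size
  k <- which.min((xs - p[1])^2 + (ys - p[2])^2)
  c(ok[k, 1], ok[k, 2])
}
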