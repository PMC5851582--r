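#' Place pour points along the shoreline
#'
#' Pour points sit at regular arc-length intervals along the shoreline
#' polyline: the first at `spacing / 2`, then every `spacing` meters, giving
#' `floor(length / spacing)` points. A closed-loop shoreline wraps without a
#' duplicate at the seam.
#'
#' @param shoreline [feature_set()] with LineString(s), or a coordinate matrix.
#' @param spacing alongshore spacing (m), the nominal flow-tube width.
#' @return data.frame: `id`, `x`, `y`, `s` (alongshore arc length, m).
#' @export
place_pour_points <- function(shoreline, spacing) {
  co <- shoreline_coords(shoreline)
  if (nrow(co) < 2) stop("degenerate shoreline")
  seg <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  L <- sum(seg)
  if (L < spacing) stop("shoreline shorter than pour-point spacing")
  closed <- isTRUE(all.equal(co[1, ], co[nrow(co), ], check.attributes = FALSE))
  npts <- floor(L / spacing)
  s <- spacing / 2 + (seq_len(npts) - 1) * spacing
  if (closed) s <- s[s < L]
  cum <- c(0, cumsum(seg))
  pts <- t(vapply(s, function(si) {
    k <- findInterval(si, cum, rightmost.closed = TRUE)
    k <- min(k, length(seg))
    t <- (si - cum[k]) / seg[k]
    co[k, ] + t * (co[k + 1, ] - co[k, ])
  }, numeric(2)))
  data.frame(id = seq_along(s), x = pts[, 1], y = pts[, 2], s = s)
}

#' Trace groundwater flow paths by reverse particle tracking
#'
#' Integrates the negated Darcy velocity field from each seed with fixed-step
#' second-order Runge-Kutta (midpoint) steps and bilinear velocity
#' interpolation between cell centers, until the particle leaves the active
#' area, reaches a stagnation point, or hits the step cap.
#'
#' @param flow a `flow_field` from [darcy_flow()].
#' @param seeds data.frame with `x`, `y` columns (pour points).
#' @param step step length as a fraction of the cell size.
#' @param max_steps step cap per path.
#' @param stag_tol speed (fraction of the domain median speed) below which a
#'   particle is declared stagnant.
#' @return list of paths; each is a list with `vertices` (n x 2 matrix) and
#'   `status` (`"exited"`, `"stagnant"` or `"capped"`).
#' @export
trace_flowpaths <- function(flow, seeds, step = 0.4, max_steps = 4000,
                            stag_tol = 1e-6) {
  grid <- flow$grid
  a <- grid$cell_size
  vc <- cell_velocities(flow)
  act <- !is.na(grid$values)
  speeds <- sqrt(vc$vx^2 + vc$vy^2)
  vref <- stats::median(speeds[act & !flow$fixed], na.rm = TRUE)
  eps <- max(vref * stag_tol, .Machine$double.xmin)
  h <- step * a
  lapply(seq_len(nrow(seeds)), function(k) {
    p <- c(seeds$x[k], seeds$y[k])
    verts <- matrix(p, 1)
    status <- "capped"
    for (it in seq_len(max_steps)) {
      v1 <- -bilinear_vel(vc, grid, p)
      sp1 <- sqrt(sum(v1^2))
      if (is.na(sp1) || sp1 < eps) { status <- "stagnant"; break }
      mid <- p + h / 2 * v1 / sp1
      v2 <- -bilinear_vel(vc, grid, mid)
      sp2 <- sqrt(sum(v2^2))
      if (is.na(sp2) || sp2 < eps) { status <- "stagnant"; break }
      p2 <- p + h * v2 / sp2
      rc <- cell_of(grid, matrix(p2, 1))
      if (is.na(rc[1]) || !act[rc[1], rc[2]]) { status <- "exited"; break }
      p <- p2
      verts <- rbind(verts, p)
    }
    list(vertices = verts, status = status)
  })
}

# cell-center velocities (m/yr per unit width) from face fluxes
cell_velocities <- function(flow) {
  a <- flow$grid$cell_size
  nr <- nrow(flow$grid$values); nc <- ncol(flow$grid$values)
  qx <- flow$qx; qy <- flow$qy
  qx[is.na(qx)] <- 0; qy[is.na(qy)] <- 0
  qxw <- cbind(0, qx); qxe <- cbind(qx, 0)
  qys <- rbind(0, qy); qyn <- rbind(qy, 0)
  list(vx = (qxw + qxe) / (2 * a), vy = (qys + qyn) / (2 * a))
}

bilinear_vel <- function(vc, grid, p) {
  c(bilinear_at(vc$vx, grid, p), bilinear_at(vc$vy, grid, p))
}

# bilinear interpolation of a value matrix at point p, clamped to the grid;
# NA neighbors get their weight renormalized over the valid ones
bilinear_at <- function(m, grid, p) {
  a <- grid$cell_size
  nr <- nrow(m); nc <- ncol(m)
  fx <- (p[1] - grid$origin[1]) / a - 0.5
  fy <- (p[2] - grid$origin[2]) / a - 0.5
  j0 <- floor(fx); i0 <- floor(fy)
  tx <- fx - j0; ty <- fy - i0
  j0 <- min(max(j0 + 1, 1), nc); i0 <- min(max(i0 + 1, 1), nr)
  j1 <- min(j0 + 1, nc); i1 <- min(i0 + 1, nr)
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  v <- c(m[i0, j0], m[i0, j1], m[i1, j0], m[i1, j1])
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Delineate flow tubes between adjacent flow paths
#'
#' Tube `k` is the band bounded by reverse-tracked paths `k` and `k + 1`
#' (clipped to `inland_extent` from the shoreline) closed by the shoreline arc
#' between their seeds and by a segment joining their inland endpoints. Every
#' land cell of the coastal strip is assigned to exactly one tube: by
#' point-in-polygon where a band encloses its center, cells on a boundary
#' line going to the tube on the left looking inland, and remaining strip
#' cells attaching to the tube of the nearest assigned cell (logged). The
#' tube's pour point is the alongshore midpoint between its bounding seeds.
#'
#' @param paths list from [trace_flowpaths()] (ordered alongshore).
#' @param shoreline shoreline [feature_set()] or coordinate matrix.
#' @param grid land [raster_grid()] whose active cells are to be partitioned.
#' @param inland_extent coastal strip depth (m), e.g. 1000 (wet) / 3500 (dry).
#' @return a `flow_tubes` list: `assignment` (integer matrix over the grid),
#'   `tubes` (data.frame id/pour x/y), `strip` (logical matrix), `n_unassigned`.
#' @export
delineate_flow_tubes <- function(paths, shoreline, grid, inland_extent) {
  if (length(paths) < 2) stop("need >= 2 flow paths")
  if (inland_extent <= 0) stop("inland_extent must be > 0")
  co <- shoreline_coords(shoreline)
  dshore <- distance_to_shore(co, grid)
  act <- !is.na(grid$values)
  strip <- act & dshore$values <= inland_extent
  check_paths_cross(paths)

  clip <- lapply(paths, function(p) clip_path(p$vertices, co, inland_extent))
  nt <- length(paths) - 1L
  assignment <- matrix(NA_integer_, nrow(grid$values), ncol(grid$values))
  cells <- which(strip, arr.ind = TRUE)
  xy <- cbind(grid$origin[1] + (cells[, 2] - 0.5) * grid$cell_size,
              grid$origin[2] + (cells[, 1] - 0.5) * grid$cell_size)
  seed_s <- vapply(paths, function(p) arc_position(p$vertices[1, ], co), 0)
  for (k in seq_len(nt)) {
    poly <- band_polygon(clip[[k]], clip[[k + 1]], co, seed_s[k], seed_s[k + 1])
    inside <- mgcv::in.out(poly, xy) > 0
    take <- inside & is.na(assignment[cells])  # left tube wins on shared lines
    assignment[cells[take, , drop = FALSE]] <- k
  }
  un <- which(strip & is.na(assignment), arr.ind = TRUE)
  n_un <- nrow(un)
  if (n_un) {
    asg <- which(!is.na(assignment), arr.ind = TRUE)
    if (!nrow(asg)) stop("no strip cell fell inside any tube band")
    for (r in seq_len(n_un)) {
      d2 <- (asg[, 1] - un[r, 1])^2 + (asg[, 2] - un[r, 2])^2
      assignment[un[r, 1], un[r, 2]] <- assignment[asg[which.min(d2), , drop = FALSE]]
    }
    message("delineate_flow_tubes: attached ", n_un,
            " unassigned strip cell(s) to the nearest tube")
  }
  pour_s <- (seed_s[-length(seed_s)] + seed_s[-1]) / 2
  pp <- t(vapply(pour_s, function(si) point_at_arc(co, si), numeric(2)))
  structure(list(assignment = assignment,
                 tubes = data.frame(id = seq_len(nt), x = pp[, 1], y = pp[, 2],
                                    s = pour_s),
                 strip = strip, n_unassigned = n_un, grid = grid),
            class = "flow_tubes")
}

check_paths_cross <- function(paths) {
  for (k in seq_len(length(paths) - 1L)) {
    v1 <- paths[[k]]$vertices; v2 <- paths[[k + 1]]$vertices
    # coarse check: sample segments
    s1 <- seq(1, nrow(v1) - 1, by = max(1, (nrow(v1) - 1) %/% 50))
    s2 <- seq(1, nrow(v2) - 1, by = max(1, (nrow(v2) - 1) %/% 50))
    for (i in s1) for (j in s2) {
      if (segments_cross(v1[i, ], v1[i + 1, ], v2[j, ], v2[j + 1, ]))
        stop("flow paths ", k, " and ", k + 1, " cross; tube delineation invalid")
    }
  }
  invisible(TRUE)
}

clip_path <- function(verts, shore, inland_extent) {
  d <- vapply(seq_len(nrow(verts)), function(i)
    point_shore_distance(verts[i, ], shore), 0)
  keep <- which(d <= inland_extent)
  if (!length(keep)) return(verts[1, , drop = FALSE])
  verts[seq_len(max(keep)), , drop = FALSE]
}

point_shore_distance <- function(p, co) {
  dmin <- Inf
  for (s in seq_len(nrow(co) - 1)) {
    v <- co[s + 1, ] - co[s, ]
    L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else min(max(sum((p - co[s, ]) * v) / L2, 0), 1)
    dmin <- min(dmin, sum((p - co[s, ] - t * v)^2))
  }
  sqrt(dmin)
}

arc_position <- function(p, co) {
  seg <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  cum <- c(0, cumsum(seg))
  best <- c(Inf, 0)
  for (s in seq_len(nrow(co) - 1)) {
    v <- co[s + 1, ] - co[s, ]
    L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else min(max(sum((p - co[s, ]) * v) / L2, 0), 1)
    d2 <- sum((p - co[s, ] - t * v)^2)
    if (d2 < best[1]) best <- c(d2, cum[s] + t * sqrt(L2))
  }
  best[2]
}

point_at_arc <- function(co, si) {
  seg <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  cum <- c(0, cumsum(seg))
  k <- min(findInterval(si, cum, rightmost.closed = TRUE), length(seg))
  t <- (si - cum[k]) / seg[k]
  co[k, ] + t * (co[k + 1, ] - co[k, ])
}

band_polygon <- function(path1, path2, shore, s1, s2) {
  # shoreline arc from s1 to s2
  seg <- sqrt(diff(shore[, 1])^2 + diff(shore[, 2])^2)
  cum <- c(0, cumsum(seg))
  lo <- min(s1, s2); hi <- max(s1, s2)
  mid_idx <- which(cum > lo & cum < hi)
  arc <- rbind(point_at_arc(shore, lo), shore[mid_idx, , drop = FALSE],
               point_at_arc(shore, hi))
  if (s1 > s2) arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
  ring <- rbind(path1[rev(seq_len(nrow(path1))), , drop = FALSE],  # inland -> seed1
                arc,                                               # seed1 -> seed2
                path2)                                             # seed2 -> inland
  ring <- rbind(ring, ring[1, ])
  ring[!duplicated(round(ring, 9)) | seq_len(nrow(ring)) == nrow(ring), , drop = FALSE]
}

#' Aggregate water and nutrient fluxes per flow tube
#'
#' Sums each flux raster over the member cells of every tube and allocates
#' any upslope inflow (water and nutrients recharged inland of the coastal
#' strip) across tubes, by default proportionally to each tube's own coastal
#' water flux (`"water"`), or proportionally to member-cell count
#' (`"width"`). Totals over tubes equal strip totals plus upslope inflow
#' exactly.
#'
#' @param tubes a `flow_tubes` object from [delineate_flow_tubes()].
#' @param water recharge volume [raster_grid()] (m3 yr-1 per cell).
#' @param n_bg,n_anth,p_bg,p_anth nutrient flux rasters (kg yr-1 per cell).
#' @param upslope named list of scalar inflows
#'   (`water`, `n_bg`, `n_anth`, `p_bg`, `p_anth`), default all 0.
#' @param allocation `"water"` or `"width"`.
#' @return data.frame, one row per tube: pour-point coordinates, member cell
#'   count, `water_flux` and the four nutrient fluxes, plus totals
#'   `n_flux`/`p_flux`.
#' @export
zone_budget <- function(tubes, water, n_bg, n_anth, p_bg, p_anth,
                        upslope = NULL, allocation = c("water", "width")) {
  allocation <- match.arg(allocation)
  check_registration(water, n_bg, n_anth, p_bg, p_anth)
  if (!all(dim(water$values) == dim(tubes$assignment)))
    stop("registration error: tube assignment does not match the flux rasters")
  up <- utils::modifyList(
    list(water = 0, n_bg = 0, n_anth = 0, p_bg = 0, p_anth = 0),
    as.list(upslope %||% list()))
  ids <- sort(unique(tubes$assignment[!is.na(tubes$assignment)]))
  sum_by <- function(r) vapply(ids, function(k)
    sum(r$values[which(tubes$assignment == k)], na.rm = TRUE), 0)
  wf <- sum_by(water)
  share <- if (allocation == "water" && sum(wf) > 0) wf / sum(wf) else {
    cnt <- vapply(ids, function(k) sum(tubes$assignment == k, na.rm = TRUE), 0)
    cnt / sum(cnt)
  }
  out <- data.frame(
    id = ids,
    x = tubes$tubes$x[match(ids, tubes$tubes$id)],
    y = tubes$tubes$y[match(ids, tubes$tubes$id)],
    n_cells = vapply(ids, function(k) sum(tubes$assignment == k, na.rm = TRUE), 0),
    water_flux = wf + up$water * share,
    n_flux_background = sum_by(n_bg) + up$n_bg * share,
    n_flux_anthropogenic = sum_by(n_anth) + up$n_anth * share,
    p_flux_background = sum_by(p_bg) + up$p_bg * share,
    p_flux_anthropogenic = sum_by(p_anth) + up$p_anth * share)
  out$n_flux <- out$n_flux_background + out$n_flux_anthropogenic
  out$p_flux <- out$p_flux_background + out$p_flux_anthropogenic
  if (any(out$water_flux < 0) || any(out$n_flux < 0) || any(out$p_flux < 0))
    stop("negative tube flux")
  class(out) <- c("tube_budget", "data.frame")
  out
}
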