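#' Groundwater recharge from the cell water balance
#'
#' Per-cell recharge depth
#' `R = P + I + OSDS - DR_fraction * P - AE - dSS` (all m yr-1), the long-term
#' balance of precipitation, irrigation, effluent leaching from onsite sewage
#' disposal systems, direct runoff (a fixed fraction of rainfall), actual
#' evapotranspiration, and soil-moisture storage change. Negative cells are
#' clipped to zero; the clip count is recorded in the `clipped` attribute and
#' logged.
#'
#' @param P precipitation [raster_grid()] (m yr-1).
#' @param AE actual evapotranspiration [raster_grid()] (m yr-1).
#' @param I irrigation (raster or scalar, m yr-1). Default 0.
#' @param OSDS effluent recharge (raster or scalar, m yr-1 equivalent).
#' @param dSS soil-moisture storage change (raster or scalar, m yr-1).
#' @param DR_fraction direct-runoff fraction of rainfall in \[0, 1\].
#' @return recharge [raster_grid()] (m yr-1) with attribute `clipped`.
#' @export
compute_recharge <- function(P, AE, I = 0, OSDS = 0, dSS = 0, DR_fraction = 0.54) {
  if (DR_fraction < 0 || DR_fraction > 1) stop("DR_fraction must be in [0, 1]")
  as_vals <- function(x) {
    if (inherits(x, "raster_grid")) { check_registration(P, x); x$values }
    else matrix(x, nrow(P$values), ncol(P$values))
  }
  r <- P$values + as_vals(I) + as_vals(OSDS) - DR_fraction * P$values -
    as_vals(AE) - as_vals(dSS)
  nclip <- sum(r < 0, na.rm = TRUE)
  if (nclip) message("compute_recharge: clipped ", nclip, " negative cell(s) to 0")
  r[r < 0] <- 0
  out <- grid_with(P, r, units = "m.yr-1")
  attr(out, "clipped") <- nclip
  out
}

#' Solve the steady-state groundwater head field
#'
#' Single-layer confined-equivalent model: solves `div(T grad h) = -w` by
#' 5-point finite differences on the active (non-nodata) cells, with Dirichlet
#' head at the coastal cells (an equivalent freshwater head, default 0 m),
#' no-flow across all other boundaries, and optional point sinks. Face
#' transmissivities are harmonic means. The sparse symmetric system is solved
#' directly.
#'
#' @param recharge recharge depth [raster_grid()] (m yr-1).
#' @param transmissivity transmissivity [raster_grid()] (m2 yr-1, > 0 on
#'   active cells).
#' @param fixed_head logical matrix marking Dirichlet cells (must include at
#'   least one active cell).
#' @param head_value Dirichlet head (m), default 0.
#' @param sinks optional [raster_grid()] of withdrawals (m3 yr-1 per cell).
#' @return a `head_field` list: `head` (raster, m), `fixed` (logical matrix),
#'   `residual` (max absolute cell mass-balance residual, m3 yr-1).
#' @export
solve_steady_head <- function(recharge, transmissivity, fixed_head,
                              head_value = 0, sinks = NULL) {
  check_registration(recharge, transmissivity)
  if (!is.null(sinks)) check_registration(recharge, sinks)
  a <- recharge$cell_size
  act <- !is.na(recharge$values) & !is.na(transmissivity$values)
  if (any(transmissivity$values[act] <= 0)) stop("transmissivity must be > 0 on active cells")
  fixed <- fixed_head & act
  if (!any(fixed)) stop("singular system: no fixed-head cell")
  nr <- nrow(act); nc <- ncol(act)
  idx <- matrix(NA_integer_, nr, nc)
  idx[act] <- seq_len(sum(act))
  n <- sum(act)

  Tm <- transmissivity$values
  # source per cell (m3/yr): recharge volume minus sinks
  b <- recharge$values * a^2
  if (!is.null(sinks)) b <- b - sinks$values
  b[!act] <- 0

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(n)
  free <- act & !fixed
  # assemble conductances for free cells; fixed cells get identity rows
  shift <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  cells <- which(free, arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]; p <- idx[i, j]
    diagv <- 0
    for (s in shift) {
      i2 <- i + s[1]; j2 <- j + s[2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || !act[i2, j2]) next
      Cf <- 2 * Tm[i, j] * Tm[i2, j2] / (Tm[i, j] + Tm[i2, j2])  # harmonic mean
      diagv <- diagv + Cf
      if (fixed[i2, j2]) {
        rhs[p] <- rhs[p] + Cf * head_value
      } else {
        ii <- c(ii, p); jj <- c(jj, idx[i2, j2]); xx <- c(xx, -Cf)
      }
    }
    ii <- c(ii, p); jj <- c(jj, p); xx <- c(xx, diagv)
    rhs[p] <- rhs[p] + b[i, j]
  }
  fx <- which(fixed & act)
  if (length(fx)) {
    p <- idx[fx]
    ii <- c(ii, p); jj <- c(jj, p); xx <- c(xx, rep(1, length(p)))
    rhs[p] <- head_value
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  h <- as.numeric(Matrix::solve(A, rhs))
  hm <- matrix(NA_real_, nr, nc)
  hm[act] <- h
  hf <- list(head = grid_with(recharge, hm, units = "m"), fixed = fixed,
             sources = b)
  hf$residual <- max(abs(divergence_residual(hf, transmissivity)))
  class(hf) <- "head_field"
  hf
}

#' Darcy face fluxes from a solved head field
#'
#' Face flux between two active cells is `-T_face * (h2 - h1)` in m3 yr-1
#' (the transmissivity already integrates over depth, and the face width
#' equals the cell size, cancelling the gradient denominator). `qx[i, j]` is
#' the flux from column `j` to `j + 1` in row `i` (positive eastward);
#' `qy[i, j]` from row `i` to `i + 1` (positive northward).
#'
#' @param head_field result of [solve_steady_head()].
#' @param transmissivity transmissivity [raster_grid()] (m2 yr-1).
#' @return a `flow_field` list: `qx` (nr x (nc-1)), `qy` ((nr-1) x nc),
#'   `grid` (the head raster for geometry), `fixed`.
#' @export
darcy_flow <- function(head_field, transmissivity) {
  h <- head_field$head$values
  Tm <- transmissivity$values
  nr <- nrow(h); nc <- ncol(h)
  hm <- function(t1, t2) 2 * t1 * t2 / (t1 + t2)
  qx <- matrix(NA_real_, nr, nc - 1)
  qy <- matrix(NA_real_, nr - 1, nc)
  if (nc > 1) {
    Tf <- hm(Tm[, -nc, drop = FALSE], Tm[, -1, drop = FALSE])
    qx <- -Tf * (h[, -1, drop = FALSE] - h[, -nc, drop = FALSE])
  }
  if (nr > 1) {
    Tf <- hm(Tm[-nr, , drop = FALSE], Tm[-1, , drop = FALSE])
    qy <- -Tf * (h[-1, , drop = FALSE] - h[-nr, , drop = FALSE])
  }
  structure(list(qx = qx, qy = qy, grid = head_field$head,
                 fixed = head_field$fixed),
            class = "flow_field")
}

# per-cell (outflow - inflow - source) over free cells, m3/yr
divergence_residual <- function(head_field, transmissivity) {
  ff <- darcy_flow(head_field, transmissivity)
  h <- head_field$head$values
  nr <- nrow(h); nc <- ncol(h)
  qx <- ff$qx; qy <- ff$qy
  qx[is.na(qx)] <- 0; qy[is.na(qy)] <- 0
  net <- matrix(0, nr, nc)
  if (nc > 1) {
    net[, -nc] <- net[, -nc] + qx       # leaving east
    net[, -1] <- net[, -1] - qx         # entering from west
  }
  if (nr > 1) {
    net[-nr, ] <- net[-nr, ] + qy
    net[-1, ] <- net[-1, ] - qy
  }
  res <- net - head_field$sources
  res[is.na(h) | head_field$fixed] <- 0
  res
}

#' Total discharge into the fixed-head (coastal) cells
#'
#' Sums Darcy fluxes across faces from free cells into fixed-head cells plus
#' any direct source on the fixed cells themselves; under steady state this
#' equals total recharge plus injection minus withdrawals.
#'
#' @param flow a `flow_field` from [darcy_flow()].
#' @param head_field the matching `head_field`.
#' @return coastal discharge in m3 yr-1.
#' @export
coastal_discharge <- function(flow, head_field) {
  fixed <- head_field$fixed
  h <- head_field$head$values
  nr <- nrow(h); nc <- ncol(h)
  tot <- 0
  qx <- flow$qx; qy <- flow$qy
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!isTRUE(fixed[i, j])) next
    if (j > 1 && isFALSE(fixed[i, j - 1]) && !is.na(qx[i, j - 1])) tot <- tot + qx[i, j - 1]
    if (j < nc && isFALSE(fixed[i, j + 1]) && !is.na(qx[i, j])) tot <- tot - qx[i, j]
    if (i > 1 && isFALSE(fixed[i - 1, j]) && !is.na(qy[i - 1, j])) tot <- tot + qy[i - 1, j]
    if (i < nr && isFALSE(fixed[i + 1, j]) && !is.na(qy[i, j])) tot <- tot - qy[i, j]
    tot <- tot + head_field$sources[i, j]  # recharge falling on the coastal cell
  }
  tot
}

#' Domain water budget
#'
#' Closes the steady-state balance
#' `dGW = R + Inj - ET - Str - Q - Cstl = 0`, solving for the coastal
#' groundwater discharge as the residual. `ET` is zero whenever the water
#' table lies deeper than the evapotranspiration extinction depth (1.5 m), the
#' usual case for these aquifers.
#'
#' @param R total recharge (m3 yr-1).
#' @param Inj injection volume (m3 yr-1).
#' @param ET evapotranspiration from the aquifer (m3 yr-1).
#' @param Str groundwater discharge to streams (m3 yr-1).
#' @param Q withdrawal (m3 yr-1).
#' @return a `water_budget` list with all components, `Cstl`, and `dGW = 0`.
#' @export
domain_water_budget <- function(R, Inj = 0, ET = 0, Str = 0, Q = 0) {
  Cstl <- R + Inj - ET - Str - Q
  if (Cstl < 0)
    stop("negative coastal discharge residual (", format(Cstl),
         " m3/yr): inconsistent budget inputs")
  structure(list(R = R, Inj = Inj, ET = ET, Str = Str, Q = Q,
                 Cstl = Cstl, dGW = 0),
            class = "water_budget")
}

#' @export
print.water_budget <- function(x, ...) {
  cat("<water_budget> (m3/yr)\n")
  for (nm in c("R", "Inj", "ET", "Str", "Q", "Cstl"))
    cat(sprintf("  %-5s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Groundwater discharge to streams, scaled by watershed area
#'
#' Baseflow to perennial streams for the wet site is anchored at a gauged
#' 0.26 m3 s-1 discharge for the reference watershed and scaled by relative
#' watershed area for the others.
#'
#' @param area_fraction watershed area as a fraction of the reference
#'   watershed's area.
#' @param reference_m3s gauged reference baseflow, m3 s-1.
#' @return m3 yr-1.
#' @export
stream_baseflow <- function(area_fraction = 1, reference_m3s = 0.26) {
  reference_m3s * area_fraction * 86400 * 365.25
}
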