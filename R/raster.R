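#' Planar raster grid
#'
#' The shared gridded data container for every field the pipeline touches
#' (rainfall, recharge, head, nutrient flux, bathymetry, drivers, predictions).
#' Coordinates are planar meters; the package never does geodesy. Values are
#' stored row-major from the lower-left corner: row `i` increases northward,
#' column `j` eastward, and the center of cell `(i, j)` sits at
#' `origin + (c(j, i) - 0.5) * cell_size`. Missing cells are held as `NA` in
#' memory; `nodata` is the sentinel used on disk.
#'
#' @param values numeric matrix (row 1 = southernmost row). Cells equal to
#'   `nodata` are converted to `NA`.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, x/y of the lower-left corner in meters.
#' @param nodata sentinel value used when writing to disk.
#' @param units free-text unit tag, e.g. `"m.yr-1"`, `"kg.yr-1"`, `"m"`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        nodata = -9999, units = "unknown") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric length 2")
  storage.mode(values) <- "double"
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(!is.finite(values) & !is.na(values)))
    stop("raster values must be finite or nodata")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         units = as.character(units)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g), units '%s'\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2], x$units))
  if (length(v))
    cat(sprintf("  valid cells: %d, range [%g, %g]\n", length(v), min(v), max(v)))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' Cell-center coordinates
#'
#' @param grid a [raster_grid()].
#' @return `grid_x`/`grid_y`: vector of column/row center coordinates;
#'   `grid_xy`: an n-cell x 2 matrix in column-major cell order.
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size

#' @rdname grid_x
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size

#' @rdname grid_x
#' @export
grid_xy <- function(grid) {
  xs <- grid_x(grid); ys <- grid_y(grid)
  cbind(x = rep(xs, each = nrow(grid$values)), y = rep(ys, ncol(grid$values)))
}

#' Locate points on a grid
#'
#' Half-open cell intervals: a point on the shared edge of two cells belongs to
#' the cell with the larger index.
#'
#' @param grid a [raster_grid()].
#' @param xy n x 2 matrix of point coordinates (m).
#' @return n x 2 integer matrix of (row, col); `NA` for points off the grid.
#' @export
cell_of <- function(grid, xy) {
  xy <- rbind(xy)
  j <- floor((xy[, 1] - grid$origin[1]) / grid$cell_size) + 1L
  i <- floor((xy[, 2] - grid$origin[2]) / grid$cell_size) + 1L
  bad <- i < 1L | i > nrow(grid$values) | j < 1L | j > ncol(grid$values)
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

#' Replace the value matrix of a grid, keeping its geometry
#' @param grid a [raster_grid()].
#' @param values replacement matrix (same dimensions).
#' @param units optional new unit tag.
#' @return a [raster_grid()].
#' @export
grid_with <- function(grid, values, units = grid$units) {
  if (!all(dim(values) == dim(grid$values)))
    stop("replacement values have wrong dimensions")
  raster_grid(values, grid$cell_size, grid$origin, grid$nodata, units)
}

#' Check that rasters share geometry
#'
#' Every pipeline stage requires its input rasters to be co-registered: same
#' dimensions, cell size, and origin. Nodata masks may differ.
#'
#' @param ... two or more [raster_grid()] objects.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
check_registration <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(g$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(g$origin, ref$origin)))
      stop("registration error: rasters do not share cell_size/origin/dimensions")
  }
  invisible(TRUE)
}

#' Read or write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows north to
#' south). The unit tag, which the ASCII grid header cannot carry, goes to a
#' JSON sidecar `<path>.aux.json`; a missing sidecar on read warns and tags the
#' grid `"unknown"`. Read-write-read round-trips are bit-exact.
#'
#' @param path file path (`.asc`).
#' @param grid if supplied, the grid is written; otherwise `path` is read.
#' @return the [raster_grid()] read, or (invisibly) the path written.
#' @export
raster_io <- function(path, grid = NULL) {
  if (is.null(grid)) read_ascii_grid(path) else write_ascii_grid(grid, path)
}

#' @rdname raster_io
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("not an ASCII grid (bad header): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("non-rectangular ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " values, got ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file is north-first
  aux <- paste0(path, ".aux.json")
  units <- "unknown"
  if (file.exists(aux)) {
    units <- jsonlite::read_json(aux)$units %||% "unknown"
  } else {
    warning("no unit sidecar for ", path, "; tagging units 'unknown'")
  }
  raster_grid(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner), nodata, units)
}

#' @rdname raster_io
#' @export
write_ascii_grid <- function(grid, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$origin[1], digits = 17)),
    paste("yllcorner", format(grid$origin[2], digits = 17)),
    paste("cellsize", format(grid$cell_size, digits = 17)),
    paste("NODATA_value", format(grid$nodata, digits = 17))), con)
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], digits = 17), collapse = " "), con)
  jsonlite::write_json(list(units = grid$units), paste0(path, ".aux.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
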