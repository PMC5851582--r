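#' Feature sets: points, lines and polygons with attributes
#'
#' Lightweight planar vector container used for land-use inventories, recharge
#' zones, shorelines and pour points. Each feature is a list with a `geometry`
#' (`type` of `"Point"`, `"LineString"` or `"Polygon"` plus a coordinate
#' matrix; polygons use the exterior ring only, closed) and a named
#' `attributes` list. Polygon rings are checked for closure and
#' self-intersection.
#'
#' @param features list of features as described above.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(features) {
  for (f in features) validate_geometry(f$geometry)
  structure(list(features = features), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type, "")
  cat("<feature_set>", length(x$features), "features:",
      paste(sprintf("%s=%d", names(table(types)), table(types)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$features)

validate_geometry <- function(g) {
  if (!g$type %in% c("Point", "LineString", "Polygon"))
    stop("unsupported geometry type: ", g$type)
  co <- g$coords
  if (g$type == "Point") {
    if (length(co) != 2L) stop("Point needs 2 coordinates")
    return(invisible(TRUE))
  }
  if (!is.matrix(co) || ncol(co) != 2L) stop(g$type, " needs an n x 2 matrix")
  if (g$type == "Polygon") {
    if (nrow(co) < 4L) stop("Polygon ring needs >= 4 vertices")
    if (!isTRUE(all.equal(co[1, ], co[nrow(co), ], check.attributes = FALSE)))
      stop("Polygon ring must be closed")
    if (ring_self_intersects(co)) stop("Polygon ring self-intersects")
  }
  invisible(TRUE)
}

# proper-crossing test for non-adjacent ring edges
ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the seam
      if (segments_cross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Polygon area by the shoelace formula
#' @param ring closed n x 2 coordinate matrix.
#' @return area in square meters (positive).
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Read or write a feature set as GeoJSON
#'
#' Standard GeoJSON `FeatureCollection` with planar coordinates. Point,
#' LineString and Polygon (exterior ring) geometries are supported.
#'
#' @param path file path (`.geojson`).
#' @param fs if supplied, written; otherwise `path` is read.
#' @return the [feature_set()] read, or (invisibly) the path written.
#' @export
geojson_io <- function(path, fs = NULL) {
  if (is.null(fs)) read_geojson(path) else write_geojson(fs, path)
}

#' @rdname geojson_io
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- lapply(j$features, function(f) {
    ty <- f$geometry$type
    co <- f$geometry$coordinates
    coords <- switch(ty,
      Point = as.numeric(unlist(co)),
      LineString = do.call(rbind, lapply(co, function(p) as.numeric(unlist(p)))),
      Polygon = do.call(rbind, lapply(co[[1]], function(p) as.numeric(unlist(p)))),
      stop("unsupported GeoJSON geometry: ", ty))
    list(geometry = list(type = ty, coords = coords),
         attributes = lapply(f$properties, function(v) if (is.null(v)) NA else v))
  })
  feature_set(feats)
}

#' @rdname geojson_io
#' @export
write_geojson <- function(fs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  feats <- lapply(fs$features, function(f) {
    co <- f$geometry$coords
    coords <- switch(f$geometry$type,
      Point = as.numeric(co),
      LineString = lapply(seq_len(nrow(co)), function(i) as.numeric(co[i, ])),
      Polygon = list(lapply(seq_len(nrow(co)), function(i) as.numeric(co[i, ]))))
    list(type = "Feature",
         geometry = list(type = f$geometry$type, coordinates = coords),
         properties = if (length(f$attributes)) f$attributes else
           structure(list(), names = character(0)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a reef survey table
#'
#' CSV with one row per survey: coordinates, benthic percent cover and fish
#' biomass columns. Records failing validation (cover outside \[0, 100\],
#' negative biomass, missing values) are dropped with a logged reason and
#' returned in the `rejected` attribute.
#'
#' @param path CSV path with a header row.
#' @param benthic,fish column names holding percent cover / biomass (g m-2).
#' @param coords column names of the x/y coordinates (m).
#' @return a `data.frame` of accepted records; attribute `rejected` holds a
#'   data.frame of dropped row indices and reasons.
#' @export
read_surveys <- function(path,
                         benthic = c("cca", "coral", "turf", "macroalgae"),
                         fish = c("browser", "grazer", "scraper", "piscivore"),
                         coords = c("x", "y")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  validate_surveys(df, benthic, fish, coords)
}

#' @rdname read_surveys
#' @param df a data.frame already in memory.
#' @export
validate_surveys <- function(df, benthic = c("cca", "coral", "turf", "macroalgae"),
                             fish = c("browser", "grazer", "scraper", "piscivore"),
                             coords = c("x", "y")) {
  need <- c(coords, benthic, fish)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  reasons <- character(nrow(df))
  for (cl in benthic) {
    bad <- is.na(df[[cl]]) | df[[cl]] < 0 | df[[cl]] > 100
    reasons[bad & reasons == ""] <- paste0(cl, " outside [0, 100]")
  }
  for (cl in fish) {
    bad <- is.na(df[[cl]]) | df[[cl]] < 0
    reasons[bad & reasons == ""] <- paste0(cl, " negative or missing")
  }
  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  if (nrow(rejected))
    message("read_surveys: rejected ", nrow(rejected), " record(s): ",
            paste(unique(rejected$reason), collapse = "; "))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}
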