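# Light-weight planar geometry over lon/lat polygons. Polygons are plain
# two-column (lon, lat) matrices; analyses at the default 0.01 deg grid
# treat coordinates as planar, which is adequate at wetland-polygon scale.

#' Read area polygons (the "datasets")
#'
#' Reads the polygons that define the datasets/areas of the study from a
#' GeoJSON FeatureCollection (one polygon Feature per dataset, identified by
#' a `dataset_id` property) or from a WKT file with one `POLYGON` per line
#' (`dataset_id;WKT` or bare WKT, in which case datasets are numbered).
#'
#' @param path file path; format detected from content (`{` starts GeoJSON).
#' @return named list of two-column (lon, lat) vertex matrices, in file order.
#' @export
read_areas <- function(path) {
  if (!file.exists(path)) stop("area file not found: ", path, call. = FALSE)
  first <- substr(trimws(readChar(path, 4096L)), 1, 1)
  if (identical(first, "{")) read_areas_geojson(path) else read_areas_wkt(path)
}

read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties$dataset_id %||% f$id %||% as.character(i)
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) {
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    }
    ring <- geom$coordinates[[1]]  # outer ring; holes unsupported
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys[[as.character(id)]] <- close_ring(m)
  }
  polys
}

read_areas_wkt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  polys <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- as.character(i)
    if (grepl(";", ln, fixed = TRUE) && !grepl("^\\s*POLYGON", ln)) {
      id <- trimws(sub(";.*$", "", ln))
      ln <- sub("^[^;]*;", "", ln)
    }
    body <- regmatches(ln, regexpr("\\(\\(.*\\)\\)", ln))
    if (length(body) == 0) stop("not a WKT POLYGON: ", ln, call. = FALSE)
    body <- gsub("[()]", "", body)
    pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    polys[[id]] <- close_ring(m)
  }
  polys
}

close_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  colnames(m) <- c("lon", "lat")
  m
}

# Point-in-polygon test for a set of points against one polygon ring.
points_in_polygon <- function(lon, lat, poly) {
  if (length(lon) == 0) return(logical(0))
  mgcv::in.out(close_ring(poly), cbind(lon, lat))
}

#' Grid cell index of coordinates
#'
#' Cells are half-open squares `[k*res, (k+1)*res)` on each axis; a
#' coordinate maps to the cell by floor division. A tiny epsilon guards the
#' floor against floating-point representation of exact multiples.
#'
#' @param lon,lat numeric vectors, decimal degrees.
#' @param res cell side in degrees.
#' @return integer matrix with columns `cell_x`, `cell_y`.
#' @export
cell_index <- function(lon, lat, res) {
  eps <- 1e-9
  cbind(cell_x = as.integer(floor(lon / res + eps)),
        cell_y = as.integer(floor(lat / res + eps)))
}

# Number of grid cells whose centre lies inside the polygon: the
# denominator of the spatial-extent feature E for that dataset.
polygon_cell_count <- function(poly, res) {
  poly <- close_ring(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  kx <- seq.int(floor(xr[1] / res) - 1L, ceiling(xr[2] / res) + 1L)
  ky <- seq.int(floor(yr[1] / res) - 1L, ceiling(yr[2] / res) + 1L)
  centres <- expand.grid(x = (kx + 0.5) * res, y = (ky + 0.5) * res)
  sum(points_in_polygon(centres$x, centres$y, poly))
}
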