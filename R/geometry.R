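# Planar geometry helpers. All coordinates are in a projected metric system;
# the study area spans well under a kilometre, so planar Euclidean distance
# is the default throughout.

#' Minimum Euclidean distance from points to a set of line features
#'
#' Computes, for each query point, the minimum point-to-segment distance over
#' all segments of a set of polylines/polygon boundaries. This is how the
#' distance-to-path and distance-to-water covariates are derived from GIS
#' feature geometry.
#'
#' @param points Two-column matrix (or data frame) of x/y coordinates in a
#'   planar metric system.
#' @param features A feature set: either a two-column coordinate matrix
#'   interpreted as one polyline, or a list of such matrices (one per
#'   polyline). See [read_features_geojson()].
#' @return Numeric vector of distances (same units as the coordinates,
#'   conventionally metres), one per query point.
#' @export
#' @examples
#' seg <- rbind(c(0, 0), c(4, 0))
#' distance_to_features(rbind(c(4, 3), c(8, 3)), seg) # 3, 5
distance_to_features <- function(points, features) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)", call. = FALSE)
  segs <- feature_segments(features)
  if (nrow(segs) == 0L) stop("empty feature set", call. = FALSE)
  d2 <- matrix(Inf, nrow(pts), nrow(segs))
  for (j in seq_len(nrow(segs))) {
    d2[, j] <- point_segment_dist2(pts, segs[j, 1:2], segs[j, 3:4])
  }
  sqrt(apply(d2, 1L, min))
}

# Flatten a feature set into a segment table (x1, y1, x2, y2).
feature_segments <- function(features) {
  if (is.matrix(features) || is.data.frame(features)) features <- list(as.matrix(features))
  if (!is.list(features)) stop("features must be a coordinate matrix or a list of them", call. = FALSE)
  if (length(features) == 0L) {
    return(matrix(numeric(0), 0L, 4L))
  }
  segs <- lapply(features, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 2L) stop("each feature must be a two-column coordinate matrix", call. = FALSE)
    n <- nrow(f)
    if (n < 2L) {
      return(matrix(numeric(0), 0L, 4L))
    }
    cbind(f[-n, 1L], f[-n, 2L], f[-1L, 1L], f[-1L, 2L])
  })
  do.call(rbind, segs)
}

# Squared distance from each row of pts to segment a--b.
point_segment_dist2 <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2)
  }
  t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(pmax(t, 0), 1)
  (pts[, 1L] - (a[1L] + t * ab[1L]))^2 + (pts[, 2L] - (a[2L] + t * ab[2L]))^2
}

#' Read line/polygon features from a GeoJSON file
#'
#' Minimal GeoJSON reader for path and river geometry: supports
#' `LineString`, `MultiLineString`, `Polygon` and `MultiPolygon` geometries
#' inside a `FeatureCollection` (or a bare geometry object). Coordinates are
#' taken verbatim, so the file should already be in a planar metric system.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of two-column coordinate matrices, one per polyline/ring,
#'   suitable for [distance_to_features()].
#' @export
read_features_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- if (identical(g$type, "FeatureCollection")) {
    lapply(g$features, function(f) f$geometry)
  } else if (identical(g$type, "Feature")) {
    list(g$geometry)
  } else {
    list(g)
  }
  out <- list()
  coord_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  }
  for (geom in geoms) {
    switch(geom$type,
      LineString = {
        out <- c(out, list(coord_mat(geom$coordinates)))
      },
      MultiLineString = {
        out <- c(out, lapply(geom$coordinates, coord_mat))
      },
      Polygon = {
        out <- c(out, lapply(geom$coordinates, coord_mat))
      },
      MultiPolygon = {
        for (poly in geom$coordinates) out <- c(out, lapply(poly, coord_mat))
      },
      stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
    )
  }
  out
}

# Point-in-polygon test (ray casting); polygon is a closed or open ring.
points_in_polygon <- function(pts, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  x <- pts[, 1L]
  y <- pts[, 2L]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  x <- poly[, 1L]
  y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}
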