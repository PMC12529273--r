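#' Vector feature layer
#'
#' A light container for point, polyline or polygon features in planar
#' metric coordinates. Geometries are two-column `(x, y)` matrices; polygon
#' rings are stored closed (first vertex repeated last) and are closed on
#' construction if supplied open.
#'
#' @param geometries list of numeric matrices with columns `x`, `y`
#'   (meters). Points may be given as length-2 vectors.
#' @param geometry_type `"point"`, `"polyline"` or `"polygon"`.
#' @param attributes optional data frame with one row per feature.
#' @param crs free-text coordinate reference tag (metadata only).
#' @return A `feature_set` object.
#' @export
feature_set <- function(geometries, geometry_type,
                        attributes = NULL, crs = "local-metric") {
  geometry_type <- match.arg(geometry_type, c("point", "polyline", "polygon"))
  geometries <- lapply(geometries, function(g) {
    if (is.numeric(g) && is.null(dim(g))) g <- matrix(g, ncol = 2, byrow = TRUE)
    g <- unname(as.matrix(g))
    if (ncol(g) != 2) stop_invalid("each geometry needs two coordinate columns (x, y)")
    if (!all(is.finite(g))) stop_invalid("all coordinates must be finite")
    if (geometry_type == "point" && nrow(g) != 1) {
      stop_invalid("point geometries must have exactly one vertex")
    }
    if (geometry_type == "polyline" && nrow(g) < 2) {
      stop_invalid("polylines need at least 2 vertices")
    }
    if (geometry_type == "polygon") {
      if (nrow(g) < 3) stop_invalid("polygon rings need at least 3 vertices")
      if (any(g[1, ] != g[nrow(g), ])) g <- rbind(g, g[1, ])  # close the ring
    }
    g
  })
  if (!is.null(attributes)) {
    attributes <- tibble::as_tibble(attributes)
    if (nrow(attributes) != length(geometries)) {
      stop_invalid("`attributes` must have one row per geometry")
    }
  }
  structure(
    list(geometry_type = geometry_type, geometries = geometries,
         attributes = attributes, crs = crs),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set:%s> %d feature(s), crs \"%s\"\n",
              x$geometry_type, length(x$geometries), x$crs))
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$geometries)

# All feature vertices stacked as one matrix (for points: the points).
feature_vertices <- function(fs) {
  if (length(fs$geometries) == 0) return(matrix(numeric(), ncol = 2))
  do.call(rbind, fs$geometries)
}

#' Convert a point feature set to a tibble of coordinates
#' @param x a point `feature_set`.
#' @param ... unused.
#' @export
as_tibble.feature_set <- function(x, ...) {
  if (x$geometry_type != "point") {
    stop_invalid("as_tibble is only defined for point feature sets")
  }
  xy <- feature_vertices(x)
  out <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  if (!is.null(x$attributes)) out <- dplyr::bind_cols(out, x$attributes)
  out
}

# Squared distance from points (px, py) to segment (x1,y1)-(x2,y2);
# vectorized over points.
dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# Even-odd ray-casting point-in-polygon, boundary-inclusive within fp noise;
# ring must be closed. Vectorized over points.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygons <- function(px, py, fs) {
  stopifnot(fs$geometry_type == "polygon")
  inside <- logical(length(px))
  for (ring in fs$geometries) {
    # cheap bbox rejection before the ray cast
    bb <- apply(ring, 2, range)
    cand <- px >= bb[1, 1] & px <= bb[2, 1] & py >= bb[1, 2] & py <= bb[2, 2]
    if (any(cand)) {
      inside[cand] <- inside[cand] | points_in_ring(px[cand], py[cand], ring)
    }
  }
  inside
}
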