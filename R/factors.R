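#' Euclidean distance raster to the nearest feature
#'
#' Fills every grid cell with the exact straight-line distance (meters)
#' from the cell center to the nearest feature: point-to-point for point
#' layers, point-to-segment for polylines. This is the raster behind the
#' distance-to-polluting-facilities and distance-to-major-roads factors.
#'
#' @param features a non-empty point or polyline [feature_set()].
#' @param grid a [make_grid()] grid.
#' @return A continuous [smc_raster()] of distances in meters.
#' @export
distance_raster <- function(features, grid) {
  if (!features$geometry_type %in% c("point", "polyline")) {
    stop_invalid("distance_raster needs a point or polyline layer")
  }
  if (length(features$geometries) == 0) {
    stop_degenerate(paste(
      "empty feature layer: no distances to compute;",
      "use a constant low-susceptibility class raster for this factor instead"
    ))
  }
  cx <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  X <- matrix(cx, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(cy, grid$n_rows, grid$n_cols)
  d2 <- matrix(Inf, grid$n_rows, grid$n_cols)
  for (g in features$geometries) {
    if (features$geometry_type == "point") {
      d2 <- pmin(d2, (X - g[1, 1])^2 + (Y - g[1, 2])^2)
    } else {
      for (k in seq_len(nrow(g) - 1)) {
        d2 <- pmin(d2, dist2_point_segment(X, Y, g[k, 1], g[k, 2],
                                           g[k + 1, 1], g[k + 1, 2]))
      }
    }
  }
  smc_raster(sqrt(d2), grid, kind = "continuous")
}

#' Classify a continuous raster into three susceptibility classes
#'
#' Cuts a continuous factor raster at two thresholds into ordinal classes
#' 1 (low), 2 (moderate), 3 (high). With `orientation = "near_is_high"`
#' (distances: closer means more exposed) and breaks `(b1, b2)`:
#' `value < b1` is high (3), `b1 <= value <= b2` moderate (2),
#' `value > b2` low (1) — the moderate class owns both endpoints, since
#' the high class is defined by a strict `< b1`. `far_is_high` reverses
#' the orientation (larger values more exposed). Nodata propagates.
#'
#' @param r a continuous [smc_raster()].
#' @param breaks strictly increasing length-2 thresholds, in the raster's
#'   units (e.g. `c(2000, 4000)` meters for facility distance,
#'   `c(100, 300)` for road distance).
#' @param orientation `"near_is_high"` (default) or `"far_is_high"`.
#' @return A class [smc_raster()] with values in 1-3 (0 = nodata).
#' @examples
#' g <- make_grid(c(0, 0, 30, 10), 10)
#' r <- smc_raster(matrix(c(1500, 3000, 5000), 1), g)
#' classify_by_breaks(r, c(2000, 4000))$values
#' @export
classify_by_breaks <- function(r, breaks, orientation = c("near_is_high", "far_is_high")) {
  orientation <- match.arg(orientation)
  if (length(breaks) != 2 || !is.numeric(breaks) || diff(breaks) <= 0) {
    stop_invalid("`breaks` must be two strictly increasing thresholds")
  }
  ok <- raster_mask(r)
  v <- r$values
  cls <- matrix(0, nrow(v), ncol(v))
  lo <- ok & v > breaks[2]
  mid <- ok & v >= breaks[1] & v <= breaks[2]
  hi <- ok & v < breaks[1]
  if (orientation == "near_is_high") {
    cls[hi] <- 3; cls[mid] <- 2; cls[lo] <- 1
  } else {
    cls[hi] <- 1; cls[mid] <- 2; cls[lo] <- 3
  }
  smc_raster(cls, r$grid, kind = "class")
}

#' Kernel density raster of point events
#'
#' Smooths a point layer into an event-density surface (events per square
#' kilometer) with a finite-support quartic kernel,
#' `f(x) = sum_p 3 / (pi h^2) * (1 - (d_p / h)^2)^2` for `d_p < h`,
#' evaluated at cell centers. The density of polluting facilities uses a
#' default bandwidth of 2000 m, the radius within which a hazardous
#' activity is taken to impact the atmosphere. A Gaussian kernel is
#' available as an alternative. For points fully interior to the grid the
#' surface integrates to the number of points (cell sums times cell area).
#'
#' @param points a point [feature_set()].
#' @param grid a [make_grid()] grid.
#' @param bandwidth kernel bandwidth h in meters (> 0); default 2000.
#' @param kernel `"quartic"` (default) or `"gaussian"` (truncated at 4h).
#' @return A continuous [smc_raster()] in events per km^2.
#' @export
kde_raster <- function(points, grid, bandwidth = 2000,
                       kernel = c("quartic", "gaussian")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop_invalid("`bandwidth` must be a positive number of meters")
  }
  if (points$geometry_type != "point") stop_invalid("`points` must be a point layer")
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (length(points$geometries) == 0) {
    warn("no points supplied: density surface is identically zero")
    return(smc_raster(vals, grid, kind = "continuous"))
  }
  cx <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  support <- if (kernel == "quartic") bandwidth else 4 * bandwidth
  pts <- feature_vertices(points)
  for (p in seq_len(nrow(pts))) {
    px <- pts[p, 1]; py <- pts[p, 2]
    js <- which(abs(cx - px) < support)
    is <- which(abs(cy - py) < support)
    if (!length(is) || !length(js)) next
    d2 <- outer((cy[is] - py)^2, (cx[js] - px)^2, "+")
    if (kernel == "quartic") {
      u2 <- d2 / bandwidth^2
      k <- ifelse(u2 < 1, 3 / (pi * bandwidth^2) * (1 - u2)^2, 0)
    } else {
      k <- exp(-d2 / (2 * bandwidth^2)) / (2 * pi * bandwidth^2)
    }
    vals[is, js] <- vals[is, js] + k
  }
  # per-m^2 kernel density expressed per km^2
  smc_raster(vals * 1e6, grid, kind = "continuous")
}

#' Min-max rescale a continuous raster to the 1-3 score range
#'
#' Linear transformation `1 + 2 * (v - vmin) / (vmax - vmin)` of the
#' non-nodata cells, mapping the observed minimum to 1 (low susceptibility)
#' and maximum to 3 (high). A constant raster maps to all 1 (low). Used for
#' the facility-density factor, which has no literature thresholds.
#'
#' @param r a continuous [smc_raster()] with at least one non-nodata cell.
#' @return A score [smc_raster()] in \[1, 3\].
#' @export
rescale_minmax_1_3 <- function(r) {
  ok <- raster_mask(r)
  if (!any(ok)) stop_degenerate("all cells are nodata: nothing to rescale")
  v <- r$values
  vmin <- min(v[ok]); vmax <- max(v[ok])
  out <- matrix(-9999, nrow(v), ncol(v))
  out[ok] <- if (vmax > vmin) 1 + 2 * (v[ok] - vmin) / (vmax - vmin) else 1
  smc_raster(out, r$grid, kind = "score", nodata = -9999)
}

#' Score a categorical land-use raster
#'
#' Maps each land-use category to a susceptibility class via an explicit
#' label-to-score table. The conventional assignment scores industrial
#' fabric (with transport and waste infrastructure) high (3), residential
#' and commercial fabric moderate (2), and natural, forested or
#' agricultural cover low (1).
#'
#' @param lu a categorical [smc_raster()] with a `categories` attribute
#'   (named codes).
#' @param mapping named integer vector, label -> score in 1-3, covering
#'   every category present in the raster.
#' @return A class [smc_raster()].
#' @export
landuse_scores <- function(lu, mapping = c(industrial = 3, residential = 2, natural = 1)) {
  if (is.null(lu$categories)) stop_invalid("`lu` must carry category labels")
  if (!all(mapping %in% 1:3)) stop_invalid("scores must be 1, 2 or 3")
  present <- names(lu$categories)[lu$categories %in% unique(as.vector(lu$values[raster_mask(lu)]))]
  unmapped <- setdiff(present, names(mapping))
  if (length(unmapped)) {
    stop_invalid(sprintf("land-use categor%s with no score mapping: %s",
                         if (length(unmapped) > 1) "ies" else "y",
                         paste(unmapped, collapse = ", ")))
  }
  code_to_score <- setNames(mapping[names(lu$categories)], lu$categories)
  cls <- matrix(0, nrow(lu$values), ncol(lu$values))
  ok <- raster_mask(lu)
  cls[ok] <- unname(code_to_score[as.character(lu$values[ok])])
  smc_raster(cls, lu$grid, kind = "class")
}

#' Score the radiation-fog factor
#'
#' Binary factor: cells whose centers fall inside a fog-prone polygon
#' (low-lying zones where nocturnal cold-air drainage pools and limits
#' pollutant dispersion) score 3 (high); all other cells 1 (low). The
#' binary factor uses only the extreme scores so that "high" means 3 for
#' every factor entering the overlay.
#'
#' @param fog_zones a polygon [feature_set()] (may be empty: all low).
#' @param grid a [make_grid()] grid.
#' @return A class [smc_raster()] with values in \{1, 3\}.
#' @export
fog_scores <- function(fog_zones, grid) {
  cls <- matrix(1, grid$n_rows, grid$n_cols)
  if (length(fog_zones$geometries)) {
    cc <- cell_centers(grid)
    inside <- points_in_polygons(cc$x, cc$y, fog_zones)
    cls[cbind(cc$row[inside], cc$col[inside])] <- 3
  }
  smc_raster(cls, grid, kind = "class")
}
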