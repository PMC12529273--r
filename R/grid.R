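#' Regular metric analysis grid
#'
#' A `grid_spec` describes a regular raster grid in planar metric
#' coordinates (a projected CRS is assumed; the CRS string is carried as
#' opaque metadata and never used in computation). Row 1 is the top of the
#' grid (maximum y), matching the usual geospatial raster layout. The
#' center of cell (row i, col j) is
#' `(x_min + (j - 0.5) * cell_size, y_max - (i - 0.5) * cell_size)`.
#'
#' @param bounds numeric length-4 vector `(x_min, y_min, x_max, y_max)` in
#'   meters.
#' @param cell_size cell edge length in meters (default 10, the working
#'   resolution of the susceptibility analysis).
#' @param crs free-text coordinate reference tag (metadata only).
#'
#' @return A `grid_spec` object with fields `x_min`, `y_max`, `n_rows`,
#'   `n_cols`, `cell_size`, `crs`. The grid anchors its top-left corner at
#'   `(x_min, y_max)` and expands right/down by whole cells, so it always
#'   covers `bounds` (`n_cols = ceiling((x_max - x_min) / cell_size)`, rows
#'   likewise).
#' @examples
#' g <- make_grid(c(0, 0, 1000, 1000), cell_size = 10)
#' g$n_rows
#' @export
make_grid <- function(bounds, cell_size = 10, crs = "local-metric") {
  if (!is.numeric(bounds) || length(bounds) != 4 || anyNA(bounds)) {
    stop_invalid("`bounds` must be numeric (x_min, y_min, x_max, y_max)")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop_invalid("`cell_size` must be a single positive number of meters")
  }
  x_min <- bounds[[1]]; y_min <- bounds[[2]]
  x_max <- bounds[[3]]; y_max <- bounds[[4]]
  if (x_max <= x_min || y_max <= y_min) {
    stop_invalid("`bounds` are inverted or zero-area: need x_max > x_min and y_max > y_min")
  }
  structure(
    list(
      x_min = x_min,
      y_max = y_max,
      n_rows = as.integer(ceiling((y_max - y_min) / cell_size - 1e-12)),
      n_cols = as.integer(ceiling((x_max - x_min) / cell_size - 1e-12)),
      cell_size = cell_size,
      crs = crs
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d rows x %d cols @ %g m, origin (%g, %g), crs \"%s\"\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_max, x$crs
  ))
  invisible(x)
}

grid_x_max <- function(g) g$x_min + g$n_cols * g$cell_size
grid_y_min <- function(g) g$y_max - g$n_rows * g$cell_size

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_max - b$y_max) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [make_grid()] grid.
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y`
#'   (cell-center coordinates, row-major order).
#' @export
cell_centers <- function(grid) {
  xs <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  tibble::tibble(
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows),
    x = rep(xs, times = grid$n_rows),
    y = rep(ys, each = grid$n_cols)
  )
}

# Half-open cell membership: a point on a shared vertical edge belongs to
# the cell to its right; on a shared horizontal edge, to the cell below.
# Returns integer row/col; NA where outside the grid extent.
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$x_min) / grid$cell_size) + 1
  row <- floor((grid$y_max - y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

default_nodata <- function(kind) {
  switch(kind,
    continuous = -9999,
    score = -9999,
    class = 0,
    categorical = 0,
    binary = 0,
    stop_invalid(sprintf("unknown raster kind \"%s\"", kind))
  )
}

#' Raster layer on a regular grid
#'
#' Couples a value matrix to a [make_grid()] grid. `kind` records the
#' semantics of the values: `continuous` (measurements such as meters or
#' events per square kilometer), `score` (continuous susceptibility in
#' \[1, 3\]), `class` (ordinal susceptibility classes 1 = low, 2 = moderate,
#' 3 = high), `categorical` (integer land-use codes with a `categories`
#' attribute), or `binary`.
#'
#' @param values numeric matrix, `n_rows` x `n_cols`, row 1 at the top.
#' @param grid a `grid_spec`.
#' @param kind one of `"continuous"`, `"score"`, `"class"`,
#'   `"categorical"`, `"binary"`.
#' @param nodata sentinel for missing cells (default -9999 for
#'   continuous/score, 0 for class/categorical/binary, so valid classes are
#'   always 1-3).
#' @param categories optional named integer vector mapping category labels
#'   to codes (categorical rasters).
#' @return An `smc_raster` object.
#' @export
smc_raster <- function(values, grid, kind = "continuous",
                       nodata = default_nodata(kind), categories = NULL) {
  if (!inherits(grid, "grid_spec")) stop_invalid("`grid` must be a grid_spec")
  if (!is.matrix(values)) stop_invalid("`values` must be a matrix")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop_invalid(sprintf(
      "values are %d x %d but the grid is %d x %d",
      nrow(values), ncol(values), grid$n_rows, grid$n_cols
    ))
  }
  r <- structure(
    list(values = values, grid = grid, kind = kind, nodata = nodata,
         categories = categories),
    class = "smc_raster"
  )
  ok <- raster_mask(r)
  v <- values[ok]
  if (kind == "score" && length(v) && (min(v) < 1 - 1e-9 || max(v) > 3 + 1e-9)) {
    stop_invalid("score raster values must lie in [1, 3]")
  }
  if (kind == "class" && length(v) && !all(v %in% c(1, 2, 3))) {
    stop_invalid("class raster values must be 1, 2 or 3")
  }
  r
}

# logical matrix of cells that carry data
raster_mask <- function(r) {
  ok <- r$values != r$nodata & is.finite(r$values)
  ok[is.na(ok)] <- FALSE
  ok
}

#' @export
print.smc_raster <- function(x, ...) {
  ok <- raster_mask(x)
  v <- x$values[ok]
  rng <- if (length(v)) sprintf("range [%g, %g]", min(v), max(v)) else "all nodata"
  cat(sprintf(
    "<smc_raster:%s> %d x %d @ %g m, %s, %d nodata cells\n",
    x$kind, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, rng, sum(!ok)
  ))
  invisible(x)
}

#' @export
as_tibble.smc_raster <- function(x, ...) {
  cc <- cell_centers(x$grid)
  cc$value <- as.vector(t(x$values))
  cc$value[cc$value == x$nodata] <- NA_real_
  cc
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Sample raster values at point locations
#'
#' Looks up, for each point, the value of the grid cell containing it under
#' half-open cell membership (a point on a shared edge belongs to the cell
#' to its right/below). Used to overlay residence points on factor and
#' susceptibility rasters.
#'
#' @param pts a data frame with columns `x` and `y` (meters), and
#'   optionally `id` used in error messages.
#' @param raster an [smc_raster()].
#' @return The input tibble with columns `value` (NA where the cell is
#'   nodata) and `nodata` (logical flag) appended.
#' @export
sample_raster <- function(pts, raster) {
  pts <- tibble::as_tibble(pts)
  ids <- if ("id" %in% names(pts)) as.character(pts$id) else as.character(seq_len(nrow(pts)))
  rc <- point_to_cell(raster$grid, pts$x, pts$y)
  if (anyNA(rc$row)) {
    bad <- which(is.na(rc$row))
    stop_bounds(sprintf(
      "%d point(s) outside the raster extent: %s",
      length(bad), paste(head(ids[bad], 5), collapse = ", ")
    ))
  }
  v <- raster$values[cbind(rc$row, rc$col)]
  nodata <- v == raster$nodata | !is.finite(v)
  v[nodata] <- NA_real_
  pts$value <- v
  pts$nodata <- nodata
  pts
}
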