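#' Read and write raster layers as Esri ASCII grids
#'
#' Rasters are exchanged as plain-text Esri ASCII grids (`.asc`), with a
#' JSON sidecar (`<file>.asc.json`) carrying the value kind, nodata
#' sentinel, CRS tag and category labels that the `.asc` header cannot
#' hold. Integer-valued rasters round-trip bit-identically; continuous
#' rasters are written with 17 significant digits and round-trip within
#' 1e-9 relative error.
#'
#' @param raster an [smc_raster()].
#' @param path output path ending in `.asc`.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns
#'   an [smc_raster()].
#' @export
write_raster <- function(raster, path) {
  if (!grepl("\\.asc$", path, ignore.case = TRUE)) {
    stop_format(sprintf("unsupported raster format for \"%s\" (expected .asc)", path))
  }
  g <- raster$grid
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10f", g$x_min),
    sprintf("yllcorner %.10f", grid_y_min(g)),
    sprintf("cellsize %.10f", g$cell_size),
    sprintf("NODATA_value %s", format(raster$nodata, scientific = FALSE))
  )
  v <- raster$values
  integral <- all(v == round(v))
  fmt_row <- function(row) {
    if (integral) paste(format(row, scientific = FALSE, trim = TRUE), collapse = " ")
    else paste(sprintf("%.17g", row), collapse = " ")
  }
  body <- vapply(seq_len(nrow(v)), function(i) fmt_row(v[i, ]), character(1))
  writeLines(c(header, body), path)
  meta <- list(kind = raster$kind, nodata = raster$nodata, crs = g$crs)
  if (!is.null(raster$categories)) meta$categories <- as.list(raster$categories)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path path to a `.asc` file written by [write_raster()] (the JSON
#'   sidecar is optional; without it the raster is read as continuous).
#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!grepl("\\.asc$", path, ignore.case = TRUE)) {
    stop_format(sprintf("unsupported raster format for \"%s\" (expected .asc)", path))
  }
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[[`, character(1), 1))
  val <- as.numeric(vapply(hdr, `[[`, character(1), 2))
  h <- setNames(val, key)
  n_rows <- as.integer(h[["nrows"]]); n_cols <- as.integer(h[["ncols"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop_format(sprintf("expected %d values, found %d", n_rows * n_cols, length(vals)))
  }
  values <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  kind <- meta$kind %||% "continuous"
  nodata <- meta$nodata %||% h[["nodata_value"]]
  categories <- if (!is.null(meta$categories)) {
    unlist(meta$categories)
  }
  grid <- make_grid(
    c(h[["xllcorner"]], h[["yllcorner"]],
      h[["xllcorner"]] + n_cols * h[["cellsize"]],
      h[["yllcorner"]] + n_rows * h[["cellsize"]]),
    cell_size = h[["cellsize"]],
    crs = meta$crs %||% "local-metric"
  )
  smc_raster(values, grid, kind = kind, nodata = nodata, categories = categories)
}

geojson_type <- c(point = "Point", polyline = "LineString", polygon = "Polygon")

#' Read and write vector layers as GeoJSON
#'
#' @param features a [feature_set()].
#' @param path output path ending in `.geojson`.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns a [feature_set()].
#' @export
write_features <- function(features, path) {
  if (!grepl("\\.geojson$", path, ignore.case = TRUE)) {
    stop_format(sprintf("unsupported vector format for \"%s\" (expected .geojson)", path))
  }
  gtype <- geojson_type[[features$geometry_type]]
  feats <- lapply(seq_along(features$geometries), function(i) {
    g <- features$geometries[[i]]
    coords <- switch(features$geometry_type,
      point = as.list(g[1, ]),
      polyline = lapply(seq_len(nrow(g)), function(k) as.list(g[k, ])),
      polygon = list(lapply(seq_len(nrow(g)), function(k) as.list(g[k, ])))
    )
    props <- if (!is.null(features$attributes)) {
      as.list(features$attributes[i, , drop = FALSE])
    } else {
      structure(list(), names = character())
    }
    list(type = "Feature",
         geometry = list(type = gtype, coordinates = coords),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", crs_tag = features$crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!grepl("\\.geojson$", path, ignore.case = TRUE)) {
    stop_format(sprintf("unsupported vector format for \"%s\" (expected .geojson)", path))
  }
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop_format("not a GeoJSON FeatureCollection")
  }
  if (length(obj$features) == 0) {
    stop_format("empty FeatureCollection: geometry type cannot be determined")
  }
  gtypes <- unique(vapply(obj$features, function(f) f$geometry$type, character(1)))
  if (length(gtypes) != 1) stop_format("mixed geometry types are not supported")
  geometry_type <- names(geojson_type)[match(gtypes, geojson_type)]
  if (is.na(geometry_type)) stop_format(sprintf("unsupported geometry type \"%s\"", gtypes))
  to_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  }
  geometries <- lapply(obj$features, function(f) {
    cc <- f$geometry$coordinates
    switch(geometry_type,
      point = matrix(c(cc[[1]], cc[[2]]), ncol = 2),
      polyline = to_mat(cc),
      polygon = to_mat(cc[[1]])
    )
  })
  props <- lapply(obj$features, function(f) f$properties)
  attributes <- if (any(lengths(props) > 0)) {
    dplyr::bind_rows(lapply(props, tibble::as_tibble))
  }
  feature_set(geometries, geometry_type, attributes = attributes,
              crs = obj$crs_tag %||% "local-metric")
}

residence_cols <- c("id", "x", "y", "group", "birth_day", "postal_centroid_id")

#' Read and write case-control residence tables
#'
#' Residences are one row per recruited newborn: an id, the planar metric
#' coordinates of the residence (a shared postal-code centroid), the group
#' label (`case` = birth defect, `control`), a birth-day index used by the
#' systematic 2:1 control sampling the cohort emulates, and the centroid
#' id. Records outside `bounds` (when given) are rejected at load time with
#' a warning naming them; a malformed group label is a validation error.
#'
#' @param path CSV path with header
#'   `id,x,y,group,birth_day,postal_centroid_id`.
#' @param bounds optional `(x_min, y_min, x_max, y_max)` study bounds used
#'   to reject out-of-area records.
#' @return A tibble of residence records.
#' @export
read_residences <- function(path, bounds = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double(),
    group = readr::col_character(),
    birth_day = readr::col_integer(),
    postal_centroid_id = readr::col_character()
  ))
  missing_cols <- setdiff(residence_cols, names(df))
  if (length(missing_cols)) {
    stop_invalid(sprintf("residence table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!df$group %in% c("case", "control"))
  if (length(bad)) {
    stop_invalid(sprintf(
      "invalid group label(s) at row(s) %s: %s (expected \"case\" or \"control\")",
      paste(head(bad, 5), collapse = ", "),
      paste(unique(df$group[bad]), collapse = ", ")
    ))
  }
  if (!is.null(bounds)) {
    out <- df$x < bounds[1] | df$x > bounds[3] | df$y < bounds[2] | df$y > bounds[4]
    if (any(out)) {
      warn(sprintf("rejected %d residence record(s) outside the study bounds: %s",
                   sum(out), paste(head(df$id[out], 5), collapse = ", ")))
      df <- df[!out, , drop = FALSE]
    }
  }
  df
}

#' @param residences a residence tibble (see [read_residences()]).
#' @rdname read_residences
#' @export
write_residences <- function(residences, path) {
  readr::write_csv(residences[, residence_cols], path)
  invisible(path)
}

#' Write or read a layer by file extension
#'
#' Dispatches on extension: `.asc` rasters, `.geojson` vector features,
#' `.csv` residence tables. Unknown extensions raise an
#' unsupported-format error.
#'
#' @param layer an [smc_raster()], [feature_set()] or residence tibble.
#' @param path destination path.
#' @return `write_layer` returns `path` invisibly; `read_layer` the object.
#' @export
write_layer <- function(layer, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = write_raster(layer, path),
    geojson = write_features(layer, path),
    csv = write_residences(layer, path),
    stop_format(sprintf("unsupported format \".%s\" for \"%s\"", ext, path))
  )
}

#' @rdname write_layer
#' @export
read_layer <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = read_raster(path),
    geojson = read_features(path),
    csv = read_residences(path),
    stop_format(sprintf("unsupported format \".%s\" for \"%s\"", ext, path))
  )
}
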