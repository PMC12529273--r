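#' Canonical factor weights for the susceptibility overlay
#'
#' The published weight column assigns: distance to polluting facilities
#' 0.37, facility density 0.37, land use 0.09, distance to major roads
#' 0.13, radiation fog 0.04. Recomputing the weights from the published
#' pairwise matrix reproduces the same multiset but with the land-use and
#' roads values transposed (land use 0.13, roads 0.09) — the matrix says
#' land use dominates roads while the published column says the reverse.
#' Both assignments are available; the published column is the pipeline
#' default, and selecting it raises a warning noting the transposition.
#'
#' @param assignment `"published"` (default) or `"recomputed"`.
#' @param quiet suppress the transposition warning.
#' @return Named weight vector over
#'   `distance, density, landuse, roads, fog`, summing to 1.
#' @export
canonical_weights <- function(assignment = c("published", "recomputed"),
                              quiet = FALSE) {
  assignment <- match.arg(assignment)
  w <- switch(assignment,
    published = c(distance = 0.37, density = 0.37, landuse = 0.09,
                  roads = 0.13, fog = 0.04),
    recomputed = c(distance = 0.37, density = 0.37, landuse = 0.13,
                   roads = 0.09, fog = 0.04)
  )
  if (assignment == "published" && !quiet) {
    warn(paste(
      "using the published weight column (land use 0.09, roads 0.13);",
      "recomputation from the published pairwise matrix assigns these two",
      "weights the other way around (see canonical_weights(\"recomputed\"))"
    ))
  }
  w
}

#' Bundled AHP pairwise matrix
#'
#' The five-criterion Saaty judgment matrix shipped with the package
#' (criteria: distance to polluting facilities, facility density, land
#' use, distance to major roads, radiation fog). Note its land-use/roads
#' pair is non-reciprocal as published (a warning is raised on load).
#'
#' @return A [pairwise_matrix()].
#' @export
bundled_ahp_matrix <- function() {
  read_pairwise_csv(system.file("extdata", "ahp_matrix.csv", package = "smcair",
                                mustWork = TRUE))
}

#' Pipeline configuration
#'
#' Collects every stage's parameters: region and cohort generation,
#' overlay weights and classing, cluster detection, and kriging. Reads
#' from YAML via [read_pipeline_config()].
#'
#' @param region a [region_config()].
#' @param cohort a [cohort_config()].
#' @param weights overlay weights (default the published column via
#'   [canonical_weights()]).
#' @param class_method susceptibility classing rule (see
#'   [classify_susceptibility()]).
#' @param distance_breaks,road_breaks class thresholds in meters.
#' @param kde_bandwidth facility-density kernel bandwidth in meters.
#' @param moran_band,moran_n_perm,moran_alpha cluster-detection settings.
#' @param krige_model,krige_neighbors,krige_cell_size kriging settings;
#'   the odds-ratio surface is predicted on its own (coarser) grid.
#' @param seed root seed expanded into per-stage seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(region = region_config(),
                            cohort = cohort_config(),
                            weights = canonical_weights(quiet = TRUE),
                            class_method = "equal_interval",
                            distance_breaks = c(2000, 4000),
                            road_breaks = c(100, 300),
                            kde_bandwidth = 2000,
                            moran_band = 4000,
                            moran_n_perm = 999,
                            moran_alpha = 0.05,
                            krige_model = "exponential",
                            krige_neighbors = 16,
                            krige_cell_size = 250,
                            seed = 1L) {
  structure(
    list(region = region, cohort = cohort, weights = weights,
         class_method = class_method, distance_breaks = distance_breaks,
         road_breaks = road_breaks, kde_bandwidth = kde_bandwidth,
         moran_band = moran_band, moran_n_perm = moran_n_perm,
         moran_alpha = moran_alpha, krige_model = krige_model,
         krige_neighbors = krige_neighbors, krige_cell_size = krige_cell_size,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [pipeline_config()], with `region` and `cohort` as nested maps.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  region_args <- y$region %||% list()
  if (!is.null(region_args$bounds)) region_args$bounds <- unlist(region_args$bounds)
  if (!is.null(region_args$landuse_fractions)) {
    region_args$landuse_fractions <- unlist(region_args$landuse_fractions)
  }
  region <- do.call(region_config, region_args)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$cluster_center)) {
    cohort_args$cluster_center <- unlist(cohort_args$cluster_center)
  }
  cohort <- do.call(cohort_config, cohort_args)
  rest <- y[setdiff(names(y), c("region", "cohort"))]
  if (!is.null(rest$weights)) rest$weights <- unlist(rest$weights)
  do.call(pipeline_config, c(list(region = region, cohort = cohort), rest))
}

run_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage \"%s\" failed: %s", stage,
                    conditionMessage(e)),
            class = "smcair_error_stage", parent = e)
    }),
    warning = function(w) {
      warn(sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
}

#' Compute the five factor score rasters for a region
#'
#' Distance to facilities and to roads are Euclidean-distance rasters
#' classified at the conventional thresholds (2000/4000 m and 100/300 m);
#' facility density is a quartic kernel density min-max rescaled onto the
#' 1-3 score range; land use is scored by category; fog is the binary
#' high/low factor. An empty facility layer takes the degenerate path:
#' all-low distance and density factors.
#'
#' @param region an [generate_region()] region (or any list with the same
#'   layers and grid).
#' @param distance_breaks,road_breaks,kde_bandwidth see
#'   [pipeline_config()].
#' @return Named list of five score/class rasters:
#'   `distance, density, landuse, roads, fog`.
#' @export
compute_factors <- function(region, distance_breaks = c(2000, 4000),
                            road_breaks = c(100, 300), kde_bandwidth = 2000) {
  grid <- region$grid
  all_low <- function() smc_raster(matrix(1, grid$n_rows, grid$n_cols), grid, "class")
  if (length(region$facilities) == 0) {
    distance <- all_low()
    density <- all_low()
  } else {
    distance <- classify_by_breaks(distance_raster(region$facilities, grid),
                                   distance_breaks, "near_is_high")
    density <- rescale_minmax_1_3(kde_raster(region$facilities, grid,
                                             bandwidth = kde_bandwidth))
  }
  roads <- if (length(region$roads) == 0) all_low() else {
    classify_by_breaks(distance_raster(region$roads, grid),
                       road_breaks, "near_is_high")
  }
  list(
    distance = distance,
    density = density,
    landuse = landuse_scores(region$landuse),
    roads = roads,
    fog = fog_scores(region$fog, grid)
  )
}

#' Run the full susceptibility and case-control analysis
#'
#' Orchestrates the end-to-end pipeline on a synthetic region: simulate
#' the region and cohort, compute the five factor rasters, combine them by
#' weighted linear combination into the susceptibility index, detect
#' case clusters with Local Moran's I, build exposure contingency tables
#' with chi-square tests and a suppression-aware frequency report, and
#' krige the case-control odds-ratio surface. Artifacts and a manifest
#' recording every stage's parameters are written under `out_dir` when
#' given; reruns with the same configuration reproduce them identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts and the
#'   manifest.
#' @param quiet suppress progress messages.
#' @return A list: `region`, `residences`, `factors`, `susceptibility`
#'   (index + classes), `moran`, `tables`, `tests` (tidy chi-square
#'   results), `report`, `kriging`, `manifest`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage_note <- function(stage, t_start) {
    say("stage %-12s done in %.1f s", stage, proc.time()[["elapsed"]] - t_start)
  }
  if (abs(sum(config$weights) - 1) > 1e-9) {
    abort(sprintf("pipeline stage \"overlay\" failed: weights must sum to 1 (got %.6f)",
                  sum(config$weights)),
          class = c("smcair_error_stage", "smcair_error_invalid_argument"))
  }
  seeds <- derive_seeds(config$seed, c("region", "cohort", "moran"))
  region_cfg <- config$region; region_cfg$seed <- seeds[["region"]]
  cohort_cfg <- config$cohort; cohort_cfg$seed <- seeds[["cohort"]]

  ts <- proc.time()[["elapsed"]]
  region <- run_stage("simulate", generate_region(region_cfg))
  residences <- run_stage("simulate", generate_residences(region, cohort_cfg))
  stage_note("simulate", ts)

  ts <- proc.time()[["elapsed"]]
  factors <- run_stage("factors", compute_factors(
    region, config$distance_breaks, config$road_breaks, config$kde_bandwidth
  ))
  stage_note("factors", ts)

  ts <- proc.time()[["elapsed"]]
  susc <- run_stage("overlay", susceptibility_map(
    factors, config$weights, method = config$class_method
  ))
  stage_note("overlay", ts)

  ts <- proc.time()[["elapsed"]]
  moran <- run_stage("moran", local_morans_i(
    residences, band = config$moran_band, n_perm = config$moran_n_perm,
    alpha = config$moran_alpha, seed = seeds[["moran"]]
  ))
  stage_note("moran", ts)

  ts <- proc.time()[["elapsed"]]
  class_layers <- run_stage("chisq", list(
    susceptibility = susc$classes,
    distance = factors$distance,
    density = classify_susceptibility(factors$density),
    landuse = factors$landuse,
    roads = factors$roads,
    fog = factors$fog
  ))
  tables <- run_stage("chisq", lapply(
    setNames(names(class_layers), names(class_layers)),
    function(nm) build_contingency(residences, class_layers[[nm]], exposure = nm)
  ))
  tests <- run_stage("chisq", dplyr::bind_rows(lapply(tables, function(tab) {
    tidy(pearson_chi2(tab))
  })))
  report <- run_stage("report", frequency_report(tables))
  stage_note("chisq", ts)

  ts <- proc.time()[["elapsed"]]
  krige_grid <- make_grid(config$region$bounds, config$krige_cell_size)
  kriging <- run_stage("krige", krige_odds_ratio(
    residences, krige_grid, model = config$krige_model,
    max_neighbors = config$krige_neighbors
  ))
  stage_note("krige", ts)

  manifest <- list(
    package = "smcair",
    version = as.character(utils::packageVersion("smcair")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    config = serialize_config(config),
    n_cases = sum(residences$group == "case"),
    n_controls = sum(residences$group == "control"),
    variogram = kriging$variogram[c("model", "nugget", "partial_sill", "range")]
  )
  result <- list(region = region, residences = residences, factors = factors,
                 susceptibility = susc, moran = moran, tables = tables,
                 tests = tests, report = report, kriging = kriging,
                 manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  say("pipeline complete in %.1f s", proc.time()[["elapsed"]] - t0)
  result
}

serialize_config <- function(config) {
  lapply(unclass(config), function(x) {
    if (inherits(x, "region_config") || inherits(x, "cohort_config")) {
      lapply(unclass(x), function(v) if (is.null(v)) NULL else unname(v))
    } else if (is.numeric(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  })
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_residences(result$residences, p("residences.csv"))
  for (nm in c("facilities", "roads", "fog", "postal_centroids")) {
    if (length(result$region[[nm]])) {
      write_features(result$region[[nm]], p(paste0(nm, ".geojson")))
    }
  }
  write_raster(result$region$landuse, p("landuse.asc"))
  for (nm in names(result$factors)) {
    write_raster(result$factors[[nm]], p(paste0("factor_", nm, ".asc")))
  }
  write_raster(result$susceptibility$index, p("susceptibility_index.asc"))
  write_raster(result$susceptibility$classes, p("susceptibility_classes.asc"))
  readr::write_csv(tibble::as_tibble(unclass(result$moran)), p("moran.csv"))
  readr::write_csv(result$tests, p("chisq.csv"))
  readr::write_csv(result$report, p("report.csv"))
  write_raster(result$kriging$surface$p_hat, p("p_hat.asc"))
  write_raster(result$kriging$surface$or, p("odds_ratio.asc"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
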