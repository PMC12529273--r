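#' Configuration of the synthetic study region
#'
#' Describes a fully synthetic study region with the structure the
#' susceptibility analysis assumes: a metric study area a few tens of km
#' across, point sources of pollution clustered on industrial land, a
#' major-road network crossing the region, a categorical land-use surface,
#' a low-lying fog-prone band along the waterfront (south) edge, and a set
#' of postal-code-like centroids that residences snap to.
#'
#' @param bounds `(x_min, y_min, x_max, y_max)` in meters; default a
#'   20 km x 15 km region.
#' @param cell_size working resolution in meters; 10 m is the analysis
#'   default, 50 m the coarse profile used for fast simulation studies.
#' @param n_facilities number of polluting facilities (point sources).
#' @param n_roads number of major roads crossing the region.
#' @param landuse_fractions named proportions for categories
#'   `industrial`, `residential`, `natural`; must sum to 1.
#' @param fog_depth_frac fraction of the region height occupied by the
#'   low-lying fog-prone band along the south edge.
#' @param n_postal_centroids number of postal-code centroids.
#' @param seed integer root seed; each layer draws from its own derived
#'   stream so changing one layer's count does not perturb the others.
#' @return A `region_config` list.
#' @export
region_config <- function(bounds = c(0, 0, 20000, 15000),
                          cell_size = 10,
                          n_facilities = 25,
                          n_roads = 8,
                          landuse_fractions = c(industrial = 0.08,
                                                residential = 0.42,
                                                natural = 0.50),
                          fog_depth_frac = 0.18,
                          n_postal_centroids = 120,
                          seed = 1L) {
  if (abs(sum(landuse_fractions) - 1) > 1e-9) {
    stop_invalid("`landuse_fractions` must sum to 1")
  }
  if (any(landuse_fractions < 0)) stop_invalid("`landuse_fractions` must be non-negative")
  counts <- c(n_facilities, n_roads, n_postal_centroids)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  structure(
    list(bounds = bounds, cell_size = cell_size, n_facilities = n_facilities,
         n_roads = n_roads, landuse_fractions = landuse_fractions,
         fog_depth_frac = fog_depth_frac,
         n_postal_centroids = n_postal_centroids, seed = as.integer(seed)),
    class = "region_config"
  )
}

#' Configuration of the synthetic case-control cohort
#'
#' Defaults reproduce the study-area sample: 164 cases (newborns with a
#' birth defect) and 209 controls. An optional planted spatial excess of
#' cases — a disk inside which the case placement intensity is multiplied
#' by `cluster_excess` — creates a known High-High cluster that the
#' cluster-detection and kriging stages should recover; with
#' `cluster_excess = 1` cases and controls are exchangeable (the planted
#' null).
#'
#' @param n_cases,n_controls group sizes (defaults 164 and 209).
#' @param cluster_center `(x, y)` center of the planted case excess, or
#'   `NULL` for none.
#' @param cluster_radius disk radius in meters (default 2000).
#' @param cluster_excess multiplier >= 1 on case intensity inside the disk.
#' @param seed integer seed for the cohort stream.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 164L, n_controls = 209L,
                          cluster_center = NULL, cluster_radius = 2000,
                          cluster_excess = 1, seed = 1L) {
  if (n_cases < 0 || n_controls < 0) stop_invalid("group sizes must be non-negative")
  if (cluster_excess < 1) stop_invalid("`cluster_excess` must be >= 1")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         cluster_center = cluster_center, cluster_radius = cluster_radius,
         cluster_excess = cluster_excess, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Derive per-layer RNG streams from one root seed so layers are
# independently reproducible. Mersenne-Twister pinned for portability.
derive_seeds <- function(seed, streams) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  setNames(sample.int(2147483646L, length(streams)), streams)
}

with_stream <- function(seed, expr) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Largest-remainder allocation of n items to proportions p (sums to n).
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic study region
#'
#' Builds all five environmental input layers on a common grid,
#' deterministically for a given seed. Land use is a patchwork of
#' contiguous category patches (jittered-lattice Voronoi with category
#' counts allocated exactly proportionally to the requested fractions, so
#' realized cell shares track the configuration closely). Facilities are
#' placed preferentially on industrial patches, roads cross the region
#' edge to edge, the fog-prone zone is a wavy low-lying band along the
#' south edge, and postal centroids snap to cell centers weighted toward
#' residential land.
#'
#' @param cfg a [region_config()].
#' @return An `smc_region` list: `grid`, `bounds`, `facilities` (points),
#'   `roads` (polylines), `landuse` (categorical raster), `fog`
#'   (polygons), `postal_centroids` (points with land-use attribute), and
#'   the `config`.
#' @export
generate_region <- function(cfg = region_config()) {
  grid <- make_grid(cfg$bounds, cfg$cell_size)
  seeds <- derive_seeds(cfg$seed, c("landuse", "facilities", "roads", "fog", "centroids"))
  width <- grid_x_max(grid) - grid$x_min
  height <- grid$y_max - grid_y_min(grid)

  # -- land use: jittered-lattice Voronoi patches ------------------------
  landuse <- with_stream(seeds[["landuse"]], {
    cats <- names(cfg$landuse_fractions)
    n_lat <- 20L  # 400 near-equal-area patches
    spacing_x <- width / n_lat; spacing_y <- height / n_lat
    sx <- grid$x_min + (rep(seq_len(n_lat), each = n_lat) - 0.5) * spacing_x +
      runif(n_lat^2, -0.45, 0.45) * spacing_x
    sy <- grid_y_min(grid) + (rep(seq_len(n_lat), times = n_lat) - 0.5) * spacing_y +
      runif(n_lat^2, -0.45, 0.45) * spacing_y
    counts <- allocate_counts(n_lat^2, cfg$landuse_fractions)
    seed_cat <- sample(rep(seq_along(cats), counts))
    cx <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
    cy <- grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
    X <- matrix(cx, grid$n_rows, grid$n_cols, byrow = TRUE)
    Y <- matrix(cy, grid$n_rows, grid$n_cols)
    best_d2 <- matrix(Inf, grid$n_rows, grid$n_cols)
    code <- matrix(1, grid$n_rows, grid$n_cols)
    for (s in seq_along(sx)) {
      d2 <- (X - sx[s])^2 + (Y - sy[s])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      code[upd] <- as.numeric(seed_cat[s])
    }
    smc_raster(code, grid, kind = "categorical",
               categories = setNames(seq_along(cats), cats))
  })

  # -- facilities: clustered on industrial land --------------------------
  facilities <- with_stream(seeds[["facilities"]], {
    n <- cfg$n_facilities
    if (n == 0) {
      feature_set(list(), "point")
    } else {
      ind_code <- landuse$categories[["industrial"]]
      ind_cells <- which(landuse$values == ind_code)
      if (length(ind_cells)) {
        pick <- ind_cells[sample.int(length(ind_cells), n, replace = TRUE)]
        rows <- (pick - 1L) %% grid$n_rows + 1L
        cols <- (pick - 1L) %/% grid$n_rows + 1L
        px <- grid$x_min + (cols - 0.5 + runif(n, -0.5, 0.5)) * grid$cell_size
        py <- grid$y_max - (rows - 0.5 + runif(n, -0.5, 0.5)) * grid$cell_size
      } else {
        px <- runif(n, grid$x_min, grid_x_max(grid))
        py <- runif(n, grid_y_min(grid), grid$y_max)
      }
      feature_set(lapply(seq_len(n), function(i) c(px[i], py[i])), "point",
                  attributes = tibble::tibble(id = sprintf("fac_%03d", seq_len(n))))
    }
  })

  # -- roads: polylines crossing edge to edge ----------------------------
  roads <- with_stream(seeds[["roads"]], {
    n <- cfg$n_roads
    if (n == 0) {
      feature_set(list(), "polyline")
    } else {
      geoms <- lapply(seq_len(n), function(i) {
        horizontal <- runif(1) < 0.5
        if (horizontal) {
          ys <- runif(2, grid_y_min(grid) + 0.05 * height, grid$y_max - 0.05 * height)
          xs <- seq(grid$x_min, grid_x_max(grid), length.out = 5)
          yy <- seq(ys[1], ys[2], length.out = 5) +
            c(0, runif(3, -0.04, 0.04) * height, 0)
          cbind(xs, yy)
        } else {
          xs <- runif(2, grid$x_min + 0.05 * width, grid_x_max(grid) - 0.05 * width)
          ys <- seq(grid$y_max, grid_y_min(grid), length.out = 5)
          xx <- seq(xs[1], xs[2], length.out = 5) +
            c(0, runif(3, -0.04, 0.04) * width, 0)
          cbind(xx, ys)
        }
      })
      feature_set(geoms, "polyline",
                  attributes = tibble::tibble(id = sprintf("road_%02d", seq_len(n))))
    }
  })

  # -- fog-prone band along the low-lying south edge ---------------------
  fog <- with_stream(seeds[["fog"]], {
    if (cfg$fog_depth_frac <= 0) {
      feature_set(list(), "polygon")
    } else {
      y0 <- grid_y_min(grid)
      depth <- cfg$fog_depth_frac * height
      xs <- seq(grid$x_min, grid_x_max(grid), length.out = 21)
      top <- y0 + depth * (1 + runif(21, -0.25, 0.25))
      ring <- rbind(
        cbind(xs, top),
        c(grid_x_max(grid), y0),
        c(grid$x_min, y0)
      )
      feature_set(list(ring), "polygon",
                  attributes = tibble::tibble(id = "fog_band"))
    }
  })

  # -- postal centroids, weighted toward residential land ----------------
  postal_centroids <- with_stream(seeds[["centroids"]], {
    n <- cfg$n_postal_centroids
    if (n == 0) {
      feature_set(list(), "point")
    } else {
      cat_w <- c(industrial = 1, residential = 4, natural = 0.3)
      cell_cat <- names(landuse$categories)[as.vector(landuse$values)]
      w <- unname(cat_w[cell_cat])
      pick <- sample.int(length(w), n, replace = FALSE, prob = w)
      rows <- (pick - 1L) %% grid$n_rows + 1L
      cols <- (pick - 1L) %/% grid$n_rows + 1L
      px <- grid$x_min + (cols - 0.5) * grid$cell_size
      py <- grid$y_max - (rows - 0.5) * grid$cell_size
      feature_set(lapply(seq_len(n), function(i) c(px[i], py[i])), "point",
                  attributes = tibble::tibble(
                    id = sprintf("pc_%04d", seq_len(n)),
                    landuse = cell_cat[pick]
                  ))
    }
  })

  structure(
    list(grid = grid, bounds = cfg$bounds, facilities = facilities,
         roads = roads, landuse = landuse, fog = fog,
         postal_centroids = postal_centroids, config = cfg),
    class = "smc_region"
  )
}

#' @export
print.smc_region <- function(x, ...) {
  cat(sprintf(
    "<smc_region> %g x %g km @ %g m cells: %d facilities, %d roads, %d postal centroids\n",
    (x$bounds[3] - x$bounds[1]) / 1000, (x$bounds[4] - x$bounds[2]) / 1000,
    x$grid$cell_size, length(x$facilities), length(x$roads),
    length(x$postal_centroids)
  ))
  invisible(x)
}

#' Generate a synthetic case-control cohort over a region
#'
#' Draws case and control residences at the region's postal centroids
#' (records share coordinates, as coarse postal-code geocoding produces).
#' Centroids on residential land receive higher placement weight; inside
#' the planted cluster disk the case weight is additionally multiplied by
#' `cluster_excess`. Cases get a birth-day index and controls draw their
#' birth day from the realized case birth days, emulating the systematic
#' same-day control sampling of the study design (matched analysis is not
#' performed downstream). With `cluster_excess = 1`, case and control
#' locations are independent draws from one distribution, so the groups
#' are exchangeable.
#'
#' @param region an [generate_region()] region.
#' @param cfg a [cohort_config()].
#' @return A tibble of residence records with columns
#'   `id, x, y, group, birth_day, postal_centroid_id`.
#' @export
generate_residences <- function(region, cfg = cohort_config()) {
  if (length(region$postal_centroids) == 0) {
    abort("region has no postal centroids: cannot place residences",
          class = "smcair_error_configuration")
  }
  cent <- as_tibble(region$postal_centroids)
  base_w <- ifelse(cent$landuse == "residential", 3, 1)
  case_w <- base_w
  if (!is.null(cfg$cluster_center) && cfg$cluster_excess > 1) {
    d2 <- (cent$x - cfg$cluster_center[1])^2 + (cent$y - cfg$cluster_center[2])^2
    case_w <- case_w * ifelse(d2 <= cfg$cluster_radius^2, cfg$cluster_excess, 1)
  }
  seeds <- derive_seeds(cfg$seed, c("cases", "controls", "birth_days"))
  i_case <- with_stream(seeds[["cases"]],
    sample.int(nrow(cent), cfg$n_cases, replace = TRUE, prob = case_w))
  i_ctrl <- with_stream(seeds[["controls"]],
    sample.int(nrow(cent), cfg$n_controls, replace = TRUE, prob = base_w))
  bd <- with_stream(seeds[["birth_days"]], {
    case_days <- sample.int(2190L, cfg$n_cases, replace = TRUE)  # 6 study years
    ctrl_days <- if (cfg$n_cases > 0) {
      sample(case_days, cfg$n_controls, replace = TRUE)
    } else {
      sample.int(2190L, cfg$n_controls, replace = TRUE)
    }
    list(case = case_days, control = ctrl_days)
  })
  dplyr::bind_rows(
    tibble::tibble(
      id = sprintf("case_%04d", seq_len(cfg$n_cases)),
      x = cent$x[i_case], y = cent$y[i_case],
      group = "case", birth_day = as.integer(bd$case),
      postal_centroid_id = cent$id[i_case]
    ),
    tibble::tibble(
      id = sprintf("ctrl_%04d", seq_len(cfg$n_controls)),
      x = cent$x[i_ctrl], y = cent$y[i_ctrl],
      group = "control", birth_day = as.integer(bd$control),
      postal_centroid_id = cent$id[i_ctrl]
    )
  )
}
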