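# Shared fixtures, cached across test files. All simulation studies run on
# the coarse 50 m profile of the default 20 km x 15 km region; cohorts use
# the default 164-case / 209-control configuration.

.fixtures <- new.env(parent = emptyenv())

coarse_region <- function() {
  if (is.null(.fixtures$region)) {
    .fixtures$region <- generate_region(region_config(cell_size = 50))
  }
  .fixtures$region
}

coarse_cohort <- function(seed = 1, ...) {
  generate_residences(coarse_region(), cohort_config(seed = seed, ...))
}

# Planted-cluster disk: centered in the region, 2 km radius, case intensity
# x4 inside. The same 100 cohorts serve the Moran recovery and the kriged
# odds-ratio elevation checks.
planted_center <- c(10000, 7500)
planted_radius <- 2000

in_disk <- function(x, y) {
  (x - planted_center[1])^2 + (y - planted_center[2])^2 <= planted_radius^2
}

planted_simulations <- function(n_seeds = 100) {
  if (!is.null(.fixtures$planted) && nrow(.fixtures$planted) >= n_seeds) {
    return(.fixtures$planted[seq_len(n_seeds), ])
  }
  reg <- coarse_region()
  krige_grid <- make_grid(reg$bounds, 500)
  cc <- cell_centers(krige_grid)
  disk_cells <- matrix(in_disk(cc$x, cc$y), krige_grid$n_rows, krige_grid$n_cols,
                       byrow = TRUE)
  rows <- lapply(seq_len(n_seeds), function(s) {
    res <- generate_residences(reg, cohort_config(
      cluster_center = planted_center, cluster_radius = planted_radius,
      cluster_excess = 4, seed = s
    ))
    m <- local_morans_i(res, band = 4000, n_perm = 999, seed = s)
    hh_in_disk <- any(m$label == "HH" & m$value == 1 & in_disk(m$x, m$y))
    k <- suppressWarnings(krige_odds_ratio(res, krige_grid))
    or <- k$surface$or$values
    case_in <- mean(in_disk(res$x[res$group == "case"], res$y[res$group == "case"]))
    ctrl_in <- mean(in_disk(res$x[res$group == "control"], res$y[res$group == "control"]))
    tibble::tibble(
      seed = s,
      hh_in_disk = hh_in_disk,
      or_inside = mean(or[disk_cells]),
      or_outside = mean(or[!disk_cells]),
      case_share_inside = case_in,
      ctrl_share_inside = ctrl_in
    )
  })
  .fixtures$planted <- dplyr::bind_rows(rows)
  .fixtures$planted
}

null_simulations <- function(n_seeds = 100) {
  if (!is.null(.fixtures$null) && nrow(.fixtures$null) >= n_seeds) {
    return(.fixtures$null[seq_len(n_seeds), ])
  }
  reg <- coarse_region()
  rows <- lapply(seq_len(n_seeds), function(s) {
    res <- generate_residences(reg, cohort_config(seed = s))
    m <- local_morans_i(res, band = 4000, n_perm = 999, seed = s)
    labelled <- m$label %in% c("HH", "LL", "HL", "LH")
    tibble::tibble(seed = s, frac_labelled = mean(labelled))
  })
  .fixtures$null <- dplyr::bind_rows(rows)
  .fixtures$null
}

# Small deterministic raster for unit tests.
toy_raster <- function(values, cell_size = 10, kind = "continuous",
                       x_min = 0, y_max = nrow(values) * cell_size) {
  g <- make_grid(c(x_min, y_max - nrow(values) * cell_size,
                   x_min + ncol(values) * cell_size, y_max), cell_size)
  smc_raster(values, g, kind = kind)
}
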