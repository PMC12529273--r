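test_that("distance rasters reproduce exact geometric distances", {
  g <- make_grid(c(25, 35, 45, 55), 10)  # single 2x2 block around (30,40)
  pt <- feature_set(list(c(0, 0)), "point")
  r <- distance_raster(pt, g)
  # cell center (30, 40): 3-4-5 triangle
  expect_equal(r$values[2, 1], 50, tolerance = 1e-6)

  g2 <- make_grid(c(45, 65, 55, 75), 10)  # single cell centered at (50, 70)
  seg <- feature_set(list(cbind(c(0, 100), c(40, 40))), "polyline")
  expect_equal(distance_raster(seg, g2)$values[1, 1], 30, tolerance = 1e-6)
})

test_that("distance raster equals the brute-force min over point-cell pairs", {
  set.seed(11)
  g <- make_grid(c(0, 0, 200, 200), 10)
  pts <- lapply(1:5, function(i) runif(2, 0, 200))
  r <- distance_raster(feature_set(pts, "point"), g)
  cc <- cell_centers(g)
  oracle <- matrix(Inf, g$n_rows, g$n_cols)
  for (p in pts) {
    d <- sqrt((cc$x - p[1])^2 + (cc$y - p[2])^2)
    oracle[cbind(cc$row, cc$col)] <- pmin(oracle[cbind(cc$row, cc$col)], d)
  }
  expect_equal(r$values, oracle, tolerance = 1e-9)
})

test_that("adding a feature never increases any cell's distance", {
  set.seed(12)
  g <- make_grid(c(0, 0, 500, 500), 50)
  pts <- lapply(1:4, function(i) runif(2, 0, 500))
  d1 <- distance_raster(feature_set(pts[1:3], "point"), g)$values
  d2 <- distance_raster(feature_set(pts, "point"), g)$values
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("an empty feature layer directs the caller to the degenerate path", {
  g <- make_grid(c(0, 0, 100, 100), 10)
  expect_error(distance_raster(feature_set(list(), "point"), g),
               class = "smcair_error_degenerate")
})

test_that("classification at the conventional breakpoints matches the class rules", {
  r <- toy_raster(matrix(c(1500, 3000, 5000), 1, 3))
  expect_equal(as.vector(classify_by_breaks(r, c(2000, 4000))$values), c(3, 2, 1))

  # moderate owns both endpoints: high is a strict < b1
  rb <- toy_raster(matrix(c(2000, 4000), 1, 2))
  expect_equal(as.vector(classify_by_breaks(rb, c(2000, 4000))$values), c(2, 2))

  roads <- toy_raster(matrix(c(50, 300, 301), 1, 3))
  expect_equal(as.vector(classify_by_breaks(roads, c(100, 300))$values), c(3, 2, 1))

  expect_error(classify_by_breaks(r, c(4000, 2000)), class = "smcair_error_invalid_argument")
})

test_that("classify then distance is invariant under translation of all inputs", {
  set.seed(13)
  g <- make_grid(c(0, 0, 400, 300), 50)
  pts <- lapply(1:3, function(i) runif(2, 0, 300))
  cls <- classify_by_breaks(distance_raster(feature_set(pts, "point"), g), c(60, 150))
  shift <- c(12345, -6789)
  g2 <- make_grid(c(shift[1], shift[2], 400 + shift[1], 300 + shift[2]), 50)
  pts2 <- lapply(pts, function(p) p + shift)
  cls2 <- classify_by_breaks(distance_raster(feature_set(pts2, "point"), g2), c(60, 150))
  expect_identical(cls2$values, cls$values)
})

test_that("quartic KDE has the analytic peak and conserves unit mass", {
  g <- make_grid(c(0, 0, 5000, 5000), 10)
  pt <- feature_set(list(c(2505, 2505)), "point")  # exactly a cell center
  k <- kde_raster(pt, g, bandwidth = 1000)
  rc <- point_to_cell(g, 2505, 2505)
  expect_equal(k$values[rc$row, rc$col], 3 / pi, tolerance = 1e-9)

  k2 <- kde_raster(pt, g, bandwidth = 500)
  mass <- sum(k2$values) * g$cell_size^2 / 1e6
  expect_equal(mass, 1, tolerance = 0.01)
  expect_true(all(k2$values >= 0))
})

test_that("KDE matches a direct double loop over points and cells", {
  set.seed(14)
  g <- make_grid(c(0, 0, 1000, 1000), 10)
  pts <- lapply(1:10, function(i) runif(2, 0, 1000))
  h <- 300
  k <- kde_raster(feature_set(pts, "point"), g, bandwidth = h)
  cc <- cell_centers(g)
  oracle <- numeric(nrow(cc))
  for (p in pts) {
    d2 <- (cc$x - p[1])^2 + (cc$y - p[2])^2
    oracle <- oracle + ifelse(d2 < h^2, 3 / (pi * h^2) * (1 - d2 / h^2)^2, 0)
  }
  got <- k$values[cbind(cc$row, cc$col)]
  expect_equal(got, oracle * 1e6, tolerance = 1e-9)
})

test_that("KDE of an empty point layer warns and returns zeros", {
  g <- make_grid(c(0, 0, 100, 100), 10)
  expect_warning(k <- kde_raster(feature_set(list(), "point"), g))
  expect_true(all(k$values == 0))
})

test_that("min-max rescaling maps onto [1, 3] preserving order", {
  r <- toy_raster(matrix(c(0, 5, 10), 1, 3))
  expect_equal(as.vector(rescale_minmax_1_3(r)$values), c(1, 2, 3))

  expect_equal(as.vector(rescale_minmax_1_3(toy_raster(matrix(7, 2, 2)))$values),
               rep(1, 4))

  set.seed(15)
  v <- matrix(runif(100), 10, 10)
  out <- rescale_minmax_1_3(toy_raster(v))$values
  expect_equal(range(out), c(1, 3))
  expect_equal(cor(as.vector(v), as.vector(out), method = "spearman"), 1)
  expect_equal(out, 1 + 2 * (v - min(v)) / (max(v) - min(v)), tolerance = 1e-12)

  allna <- toy_raster(matrix(-9999, 2, 2))
  expect_error(rescale_minmax_1_3(allna), class = "smcair_error_degenerate")
})

test_that("land-use scoring maps categories and rejects unmapped ones", {
  g <- make_grid(c(0, 0, 30, 10), 10)
  lu <- smc_raster(matrix(c(1, 2, 3), 1, 3), g, kind = "categorical",
                   categories = c(industrial = 1, residential = 2, natural = 3))
  out <- landuse_scores(lu)
  expect_equal(as.vector(out$values), c(3, 2, 1))

  lu2 <- smc_raster(matrix(c(1, 4), 1, 2), g <- make_grid(c(0, 0, 20, 10), 10),
                    kind = "categorical",
                    categories = c(industrial = 1, wetland = 4))
  expect_error(landuse_scores(lu2), regexp = "wetland",
               class = "smcair_error_invalid_argument")
})

test_that("fog scoring is binary on the extreme classes", {
  g <- make_grid(c(0, 0, 40, 40), 10)
  band <- feature_set(list(cbind(c(0, 40, 40, 0), c(0, 0, 15, 15))), "polygon")
  out <- fog_scores(band, g)
  expect_true(all(out$values %in% c(1, 3)))
  expect_equal(out$values[4, 1], 3)  # center (5, 5): inside
  expect_equal(out$values[1, 1], 1)  # center (5, 35): outside

  empty <- fog_scores(feature_set(list(), "polygon"), g)
  expect_true(all(empty$values == 1))
})

test_that("every factor raster of a generated region stays within its range", {
  reg <- generate_region(region_config(
    bounds = c(0, 0, 5000, 4000), cell_size = 50, seed = 3
  ))
  factors <- compute_factors(reg)
  for (nm in names(factors)) {
    f <- factors[[nm]]
    v <- f$values[raster_mask(f)]
    if (f$kind == "class") expect_true(all(v %in% 1:3), label = nm)
    else expect_true(all(v >= 1 - 1e-9 & v <= 3 + 1e-9), label = nm)
  }
})
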