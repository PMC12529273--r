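test_that("empirical semivariogram matches direct formulas on small cases", {
  two <- tibble::tibble(x = c(0, 100), y = 0, value = c(0, 1))
  emp <- empirical_variogram(two, n_bins = 1, max_lag = 150)
  expect_equal(nrow(emp), 1)
  expect_equal(emp$gamma, 0.5)
  expect_equal(emp$n_pairs, 1L)

  const <- tibble::tibble(x = runif(10, 0, 100), y = runif(10, 0, 100), value = 2)
  emp2 <- empirical_variogram(const, n_bins = 5)
  expect_true(all(emp2$gamma == 0))

  coincident <- tibble::tibble(x = 1, y = 1, value = c(0, 1, 0))
  expect_error(empirical_variogram(coincident), class = "smcair_error_degenerate")
})

test_that("binned semivariances equal an O(n^2) pair loop", {
  set.seed(61)
  pts <- tibble::tibble(x = runif(30, 0, 1000), y = runif(30, 0, 1000),
                        value = rnorm(30))
  n_bins <- 8
  max_lag <- 600
  emp <- empirical_variogram(pts, n_bins = n_bins, max_lag = max_lag)
  edges <- seq(0, max_lag, length.out = n_bins + 1)
  acc <- numeric(n_bins); cnt <- integer(n_bins)
  for (i in 1:29) for (j in (i + 1):30) {
    h <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
    if (h <= max_lag) {
      b <- max(1, findInterval(h, edges, rightmost.closed = TRUE))
      acc[b] <- acc[b] + (pts$value[i] - pts$value[j])^2
      cnt[b] <- cnt[b] + 1L
    }
  }
  keep <- cnt > 0
  expect_equal(emp$gamma, (acc / (2 * pmax(cnt, 1)))[keep], tolerance = 1e-12)
  expect_equal(emp$n_pairs, cnt[keep])
})

test_that("variogram fitting recovers known parameters", {
  truth <- variogram_model("exponential", nugget = 0.05, partial_sill = 0.20,
                           range = 3000)
  h <- seq(100, 6000, length.out = 20)
  emp <- tibble::tibble(lag = h, gamma = variogram_gamma(h, truth),
                        n_pairs = rep(50L, 20))
  fit <- fit_variogram(emp, "exponential")
  expect_lt(abs(fit$nugget - 0.05) / 0.05, 0.15)
  expect_lt(abs(fit$partial_sill - 0.20) / 0.20, 0.15)
  expect_lt(abs(fit$range - 3000) / 3000, 0.15)
})

test_that("a flat empirical variogram fits as pure nugget", {
  emp <- tibble::tibble(lag = c(100, 500, 1000, 2000), gamma = 0.25,
                        n_pairs = rep(40L, 4))
  fit <- fit_variogram(emp, "exponential")
  expect_lt(fit$partial_sill, 0.02)
  expect_equal(fit$nugget, 0.25, tolerance = 0.02)

  expect_error(fit_variogram(emp[1:2, ]), class = "smcair_error_invalid_argument")
})

test_that("kriging with zero nugget interpolates the data exactly", {
  set.seed(62)
  pts <- tibble::tibble(
    x = c(105, 405, 705, 305, 855), y = c(105, 155, 655, 905, 455),
    value = rnorm(5)
  )
  vg <- variogram_model("exponential", nugget = 0, partial_sill = 1, range = 800)
  g <- make_grid(c(0, 0, 1000, 1000), 10)  # data points sit on cell centers
  surf <- ordinary_krige(pts, g, vg)
  got <- sample_raster(pts, surf)$value
  expect_equal(got, pts$value, tolerance = 1e-6)
})

test_that("kriging a constant field returns the constant everywhere", {
  pts <- tibble::tibble(x = c(0, 500, 900, 200), y = c(0, 100, 800, 700), value = 3.5)
  vg <- variogram_model("spherical", nugget = 0.1, partial_sill = 0.5, range = 600)
  surf <- ordinary_krige(pts, make_grid(c(0, 0, 1000, 1000), 100), vg)
  expect_true(all(abs(surf$values - 3.5) < 1e-9))
})

test_that("kriging weights match an independent dense linear solve", {
  set.seed(63)
  pts <- tibble::tibble(x = runif(5, 0, 1000), y = runif(5, 0, 1000),
                        value = rnorm(5))
  vg <- variogram_model("exponential", nugget = 0.02, partial_sill = 0.3, range = 500)
  g <- make_grid(c(420, 380, 440, 400), 20)  # single prediction cell at (430, 390)
  got <- ordinary_krige(pts, g, vg)$values[1, 1]

  # oracle: assemble and solve the full ordinary-kriging system directly
  G <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    h <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
    G[i, j] <- if (h == 0 && i == j) 0 else
      vg$nugget + vg$partial_sill * (1 - exp(-3 * h / vg$range))
  }
  A <- rbind(cbind(G, 1), c(rep(1, 5), 0))
  h0 <- sqrt((pts$x - 430)^2 + (pts$y - 390)^2)
  b <- c(vg$nugget + vg$partial_sill * (1 - exp(-3 * h0 / vg$range)), 1)
  lambda <- solve(A, b)[1:5]
  expect_equal(sum(lambda), 1, tolerance = 1e-9)
  expect_equal(got, sum(lambda * pts$value), tolerance = 1e-9)
})

test_that("coincident points with zero nugget jitter or fail as configured", {
  pts <- tibble::tibble(x = c(100, 100, 500), y = c(100, 100, 500),
                        value = c(0, 1, 1))
  vg <- variogram_model("exponential", nugget = 0, partial_sill = 1, range = 300)
  g <- make_grid(c(0, 0, 600, 600), 200)
  expect_warning(ordinary_krige(pts, g, vg), regexp = "jitter")
  expect_error(ordinary_krige(pts, g, vg, duplicates = "fail"),
               class = "smcair_error_singular")
  # a positive nugget regularizes the system without jitter
  vg2 <- variogram_model("exponential", nugget = 0.1, partial_sill = 1, range = 300)
  expect_silent(ordinary_krige(pts, g, vg2))
})

test_that("odds-ratio surface transforms probabilities against study-wide odds", {
  g <- make_grid(c(0, 0, 30, 10), 10)
  p <- smc_raster(matrix(c(164 / 373, 0.6, 0), 1, 3), g)
  or <- odds_ratio_surface(p, n_cases = 164, n_controls = 209)
  expect_equal(or$baseline_odds, 164 / 209, tolerance = 1e-12)
  expect_equal(or$or$values[1, 1], 1, tolerance = 1e-9)

  # p = 0.6 against baseline odds 1: OR = 1.5
  or2 <- odds_ratio_surface(p, n_cases = 100, n_controls = 100)
  expect_equal(or2$or$values[1, 2], 1.5, tolerance = 1e-9)

  # p = 0 is clipped, OR stays positive and finite
  expect_gt(or$or$values[1, 3], 0)
  expect_lt(or$or$values[1, 3], 1e-4)
  expect_error(odds_ratio_surface(p, 100, 0), class = "smcair_error_invalid_argument")
})

test_that("the OR surface is a monotone transform of the kriged probability", {
  res <- coarse_cohort(seed = 7)
  g <- make_grid(coarse_region()$bounds, 1000)
  k <- suppressWarnings(krige_odds_ratio(res, g))
  p <- as.vector(k$surface$p_hat$values)
  or <- as.vector(k$surface$or$values)
  expect_equal(cor(p, or, method = "spearman"), 1)
})

test_that("a planted case excess elevates the kriged OR inside the disk", {
  sims <- planted_simulations(100)
  expect_gte(sum(sims$or_inside > sims$or_outside), 95)
})
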