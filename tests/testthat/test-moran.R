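test_that("distance-band neighbors follow the geometry", {
  pts <- tibble::tibble(x = c(0, 3000, 9000), y = 0)
  w <- distance_band_weights(pts, band = 4000)
  expect_equal(w$neighbors[[1]], 2L)
  expect_equal(w$neighbors[[2]], 1L)
  expect_length(w$neighbors[[3]], 0)

  far <- tibble::tibble(x = c(0, 10000, 20000), y = 0)
  wf <- distance_band_weights(far, band = 4000)
  expect_true(all(lengths(wf$neighbors) == 0))
})

test_that("coincident points are mutual neighbors but never self-neighbors", {
  pts <- tibble::tibble(x = c(100, 100, 5000), y = c(200, 200, 200))
  w <- distance_band_weights(pts, band = 4000)
  expect_equal(w$neighbors[[1]], 2L)
  expect_equal(w$neighbors[[2]], 1L)
  expect_false(any(vapply(seq_len(3), function(i) i %in% w$neighbors[[i]], logical(1))))
})

test_that("neighbor lists equal a brute-force O(n^2) distance check", {
  set.seed(41)
  pts <- tibble::tibble(x = runif(50, 0, 10000), y = runif(50, 0, 10000))
  band <- 2500
  w <- distance_band_weights(pts, band)
  for (i in 1:50) {
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
    expect_equal(sort(w$neighbors[[i]]), setdiff(which(d <= band), i))
    if (length(w$neighbors[[i]])) {
      expect_equal(sum(w$weights[[i]]), 1, tolerance = 1e-12)
    }
  }
})

test_that("constant marks are a zero-variance error", {
  pts <- tibble::tibble(x = c(0, 100, 200), y = 0, value = 1)
  expect_error(local_morans_i(pts, n_perm = 99), class = "smcair_error_degenerate")
})

test_that("four mutually-neighboring points match hand evaluation and exhaustive permutation", {
  pts <- tibble::tibble(
    x = c(0, 100, 0, 100), y = c(0, 0, 100, 100),
    value = c(1, 1, 0, 0)
  )
  res <- local_morans_i(pts, band = 400, n_perm = "exact", alternative = "greater")

  # hand oracle: z = (.5, .5, -.5, -.5), m2 = .25, each lag = mean of other 3
  z <- c(0.5, 0.5, -0.5, -0.5)
  m2 <- 0.25
  for (i in 1:4) {
    lag_i <- mean(z[-i])
    expect_equal(res$I[i], z[i] / m2 * lag_i, tolerance = 1e-12)
  }

  # exhaustive oracle: enumerate all 3! arrangements of the others
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in 1:4) {
    others <- z[-i]
    I_perm <- apply(perms, 1, function(p) z[i] / m2 * mean(others[p]))
    p_oracle <- sum(I_perm >= res$I[i] - 1e-12) / nrow(perms)
    expect_equal(res$p_value[i], p_oracle, tolerance = 1e-12)
  }
})

test_that("local statistics average to the global Moran's I", {
  set.seed(43)
  # large band: no isolated points, every row standardized to sum 1
  pts <- tibble::tibble(x = runif(40, 0, 5000), y = runif(40, 0, 5000),
                        value = rbinom(40, 1, 0.4))
  w <- distance_band_weights(pts, band = 10000)
  expect_true(all(lengths(w$neighbors) > 0))
  res <- local_morans_i(pts, weights = w, n_perm = 99, seed = 1)
  n <- nrow(pts)
  z <- pts$value - mean(pts$value)
  lag <- vapply(1:n, function(i) sum(w$weights[[i]] * z[w$neighbors[[i]]]), numeric(1))
  global <- (n / n) * sum(z * lag) / sum(z^2)  # S0 = n for row-standardized rows
  expect_equal(mean(res$I), global, tolerance = 1e-9)
})

test_that("deterministic outputs are equivariant under point relabeling", {
  pts <- tibble::tibble(
    x = c(0, 100, 0, 150, 40), y = c(0, 0, 100, 120, 60),
    value = c(1, 1, 0, 0, 1)
  )
  perm <- c(3, 5, 1, 2, 4)
  res <- local_morans_i(pts, band = 300, n_perm = "exact")
  res_p <- local_morans_i(pts[perm, ], band = 300, n_perm = "exact")
  expect_equal(res_p$I, res$I[perm], tolerance = 1e-12)
  expect_equal(res_p$lag, res$lag[perm], tolerance = 1e-12)
  expect_equal(res_p$p_value, res$p_value[perm], tolerance = 1e-12)
  expect_equal(res_p$label, res$label[perm])
})

test_that("isolated points are labelled, not dropped", {
  pts <- tibble::tibble(x = c(0, 100, 99000), y = 0, value = c(1, 0, 1))
  res <- local_morans_i(pts, band = 4000, n_perm = 99, seed = 2)
  expect_equal(res$label[3], "isolated")
  expect_true(is.na(res$I[3]))
  expect_true(is.na(res$p_value[3]))
})

test_that("one-tailed permutation p-values are super-uniform under the null", {
  set.seed(44)
  ps <- unlist(lapply(1:30, function(s) {
    pts <- tibble::tibble(x = runif(25, 0, 4000), y = runif(25, 0, 4000),
                          value = sample(rep(c(1, 0), c(10, 15))))
    res <- local_morans_i(pts, band = 2000, n_perm = 199, seed = s,
                          alternative = "greater")
    res$p_value[res$label != "isolated"]
  }))
  # super-uniformity: the ECDF must not sit significantly above the uniform
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted case cluster is recovered as High-High points in the disk", {
  sims <- planted_simulations(100)
  expect_gte(sum(sims$hh_in_disk), 95)
})

test_that("the null false-labeling rate stays near the nominal level", {
  sims <- null_simulations(100)
  expect_lte(mean(sims$frac_labelled), 0.075)
})
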