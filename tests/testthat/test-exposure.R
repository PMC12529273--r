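test_that("contingency tables count sampled classes with zero rows kept", {
  g <- make_grid(c(0, 0, 30, 10), 10)
  cls <- smc_raster(matrix(3, 1, 3), g, kind = "class")
  res <- tibble::tibble(
    id = c("c1", "c2", "k1"), x = c(5, 15, 25), y = 5,
    group = c("case", "case", "control")
  )
  tab <- build_contingency(res, cls, "demo")
  expect_equal(unclass(unname(tab)), rbind(c(0L, 0L), c(0L, 0L), c(2L, 1L)),
               ignore_attr = TRUE)

  empty <- build_contingency(res[0, ], cls)
  expect_true(all(unclass(empty) == 0))
})

test_that("contingency counts equal a per-point manual raster lookup", {
  reg <- coarse_region()
  res <- coarse_cohort(seed = 6)
  factors <- compute_factors(reg)
  cls <- factors$distance
  tab <- build_contingency(res, cls, "distance")
  # oracle: manual lookup per point
  rc <- point_to_cell(cls$grid, res$x, res$y)
  v <- cls$values[cbind(rc$row, rc$col)]
  for (k in 1:3) {
    expect_equal(tab[k, "case"], sum(v == k & res$group == "case"))
    expect_equal(tab[k, "control"], sum(v == k & res$group == "control"))
  }
})

test_that("residences on nodata cells go to the exclusions report", {
  g <- make_grid(c(0, 0, 20, 10), 10)
  cls <- smc_raster(matrix(c(0, 2), 1, 2), g, kind = "class")
  res <- tibble::tibble(id = c("a", "b"), x = c(5, 15), y = 5,
                        group = c("case", "control"))
  tab <- build_contingency(res, cls)
  ex <- attr(tab, "exclusions")
  expect_equal(ex$id, "a")
  expect_equal(sum(tab), 1)
})

test_that("chi-square on the published tables reproduces the published p-values", {
  tabs <- contingency_from_counts(published_exposure_counts())

  susc <- pearson_chi2(tabs$susceptibility)
  expect_equal(susc$statistic, 2.315, tolerance = 5e-4)
  expect_equal(susc$df, 2)
  expect_equal(round(susc$p_value, 3), 0.314)
  expect_equal(susc$correction, "none")

  fog <- pearson_chi2(tabs$fog)
  expect_equal(fog$correction, "yates")
  expect_equal(round(fog$p_value, 3), 0.922)
  # without the continuity correction the 2x2 p is noticeably smaller
  expect_lt(pearson_chi2(tabs$fog, correct = FALSE)$p_value, 0.8)
})

test_that("two identical columns give statistic 0 and p 1", {
  tab <- contingency_table(cbind(case = c(7, 7), control = c(7, 7)))
  out <- pearson_chi2(tab, correct = FALSE)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("the uncorrected 2x2 statistic equals the closed form", {
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(sample(1:60, 4, replace = TRUE), 2, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- pearson_chi2(contingency_table(m), correct = FALSE)$statistic
    expect_equal(got, closed, tolerance = 1e-9)
  }
})

test_that("the statistic is invariant under row and column permutation", {
  m <- rbind(c(25, 21), c(92, 123), c(47, 65))
  base <- pearson_chi2(contingency_table(m), correct = FALSE)
  perm <- pearson_chi2(contingency_table(m[c(3, 1, 2), c(2, 1)]), correct = FALSE)
  expect_equal(perm$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(perm$p_value, base$p_value, tolerance = 1e-12)
})

test_that("collapsing rows with identical case:control ratios preserves the statistic", {
  # proportional rows carry no extra association signal: merging them leaves
  # the Pearson statistic unchanged (p shifts only through the df)
  m <- rbind(c(10, 20), c(20, 40), c(30, 15))
  collapsed <- rbind(c(30, 60), c(30, 15))
  r1 <- pearson_chi2(contingency_table(m), correct = FALSE)
  r2 <- pearson_chi2(contingency_table(collapsed), correct = FALSE)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$df, 2)
  expect_equal(r2$df, 1)
  expect_equal(pchisq(r1$statistic, r1$df, lower.tail = FALSE), r1$p_value,
               tolerance = 1e-12)
})

test_that("degenerate margins raise a named error", {
  tab <- contingency_table(cbind(case = c(0, 12), control = c(0, 15)),
                           exposure = "x")
  expect_error(pearson_chi2(tab), regexp = "margin",
               class = "smcair_error_degenerate")
})

test_that("frequency report computes group percentages to one decimal", {
  tabs <- contingency_from_counts(published_exposure_counts())
  rep_out <- frequency_report(tabs$susceptibility)
  cases <- rep_out[rep_out$group == "case", ]
  expect_equal(cases$pct, c(15.2, 56.1, 28.7))
  controls <- rep_out[rep_out$group == "control", ]
  expect_equal(controls$pct, c(10.0, 58.9, 31.1))
})

test_that("statistical secrecy masks counts strictly below the threshold", {
  tab <- contingency_table(cbind(case = c(2, 3, 100), control = c(0, 50, 60)))
  rep_out <- frequency_report(tab)
  expect_true(rep_out$suppressed[rep_out$group == "case" & rep_out$class == "low"])
  expect_equal(rep_out$display[rep_out$group == "case" & rep_out$class == "low"], "<3")
  expect_false(rep_out$suppressed[rep_out$group == "case" & rep_out$class == "moderate"])
  expect_equal(rep_out$n[rep_out$group == "case" & rep_out$class == "moderate"], 3L)
  # group totals use all rows, including suppressed ones
  expect_equal(rep_out$pct[rep_out$group == "case" & rep_out$class == "high"],
               round(100 * 100 / 105, 1))
  expect_error(frequency_report(tab, suppression_threshold = -1),
               class = "smcair_error_invalid_argument")
})
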