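point_values <- function(pts) {
  if ("value" %in% names(pts)) as.numeric(pts$value)
  else if ("group" %in% names(pts)) as.numeric(pts$group == "case")
  else stop_invalid("`pts` needs a `value` or `group` column")
}

#' Empirical semivariogram
#'
#' Bins point pairs by separation distance and computes the method-of-
#' moments semivariance `gamma(h) = sum (v_i - v_j)^2 / (2 N(h))` per bin.
#' Empty bins are omitted. The default maximum lag is a third of the
#' largest pairwise distance, the usual working rule.
#'
#' @param pts data frame with `x`, `y` and a numeric `value` column (or a
#'   `group` column, converted to the case indicator 1/0).
#' @param n_bins number of equal-width lag bins (default 15).
#' @param max_lag largest pair separation considered, meters.
#' @return A tibble with columns `lag` (bin midpoint), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(pts, n_bins = 15, max_lag = NULL) {
  pts <- tibble::as_tibble(pts)
  v <- point_values(pts)
  n <- nrow(pts)
  if (n < 2) stop_invalid("need at least two points")
  d <- dist(cbind(pts$x, pts$y))
  if (max(d) == 0) stop_degenerate("all points are coincident: no spatial structure to estimate")
  max_lag <- max_lag %||% (max(d) / 3)
  if (max_lag <= 0) stop_invalid("`max_lag` must be positive")
  dv2 <- dist(v)^2  # pairwise (v_i - v_j)^2 in the same pair order as d
  # coincident pairs (snapped geocoding) stay in the first bin: they carry
  # the nugget information
  keep <- d <= max_lag
  bin <- pmax(1L, findInterval(d[keep], seq(0, max_lag, length.out = n_bins + 1),
                               rightmost.closed = TRUE))
  gamma <- tapply(dv2[keep], bin, function(s) sum(s) / (2 * length(s)))
  n_pairs <- tapply(dv2[keep], bin, length)
  mids <- (seq_len(n_bins) - 0.5) * max_lag / n_bins
  tibble::tibble(
    lag = mids[as.integer(names(gamma))],
    gamma = as.numeric(gamma),
    n_pairs = as.integer(n_pairs)
  )
}

#' Theoretical semivariogram models
#'
#' `gamma(h)` for the exponential and spherical models, parameterized by
#' nugget, partial sill and the practical range (the distance at which the
#' exponential model reaches 95% of its sill). `gamma(0) = 0`; the nugget
#' is the limit from above.
#'
#' @param h distances in meters.
#' @param model a `variogram_model` from [variogram_model()] or
#'   [fit_variogram()].
#' @return Semivariance values.
#' @export
variogram_gamma <- function(h, model) {
  c0 <- model$nugget; c1 <- model$partial_sill; a <- model$range
  g <- if (model$model == "exponential") {
    c0 + c1 * (1 - exp(-3 * h / a))
  } else {
    ifelse(h < a, c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3), c0 + c1)
  }
  g[h == 0] <- 0
  g
}

#' @param model `"exponential"` or `"spherical"`.
#' @param nugget,partial_sill,range model parameters (`range` is the
#'   practical range in meters).
#' @rdname variogram_gamma
#' @export
variogram_model <- function(model = c("exponential", "spherical"),
                            nugget = 0, partial_sill = 1, range = 1000) {
  model <- match.arg(model)
  if (nugget < 0 || partial_sill < 0 || range <= 0) {
    stop_invalid("need nugget >= 0, partial_sill >= 0, range > 0")
  }
  structure(list(model = model, nugget = nugget, partial_sill = partial_sill,
                 range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model:%s> nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$model, x$nugget, x$partial_sill, x$range))
  invisible(x)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Fits nugget, partial sill and practical range to an empirical
#' semivariogram, minimizing the pair-count-weighted sum of squared
#' deviations. A fixed multi-start grid over the range parameter feeds
#' bounded quasi-Newton refinement, so the fit is deterministic.
#'
#' @param empirical tibble from [empirical_variogram()] with at least 3
#'   non-empty bins.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @return A `variogram_model` with an added `sse` field (weighted
#'   residual).
#' @export
fit_variogram <- function(empirical, model = c("exponential", "spherical")) {
  model <- match.arg(model)
  if (nrow(empirical) < 3) {
    stop_invalid(sprintf("need at least 3 non-empty lag bins, got %d", nrow(empirical)))
  }
  h <- empirical$lag; g <- empirical$gamma; w <- empirical$n_pairs
  sill0 <- max(g)
  obj <- function(par) {
    m <- list(model = model, nugget = par[1], partial_sill = par[2], range = par[3])
    sum(w * (g - variogram_gamma(h, m))^2)
  }
  upper_range <- 10 * max(h)
  starts <- expand.grid(
    nugget = c(0, 0.5) * min(g),
    psill = c(0.5, 1) * max(sill0 - min(g), 1e-12),
    range = max(h) * c(0.1, 0.3, 0.6, 1, 2)
  )
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[s, ]), obj, method = "L-BFGS-B",
            lower = c(0, 0, max(h) * 1e-3),
            upper = c(sill0 * 2 + 1e-12, sill0 * 3 + 1e-12, upper_range)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("variogram fit did not converge from any start",
          class = "smcair_error_no_convergence")
  }
  out <- variogram_model(model, nugget = best$par[1],
                         partial_sill = best$par[2], range = best$par[3])
  out$sse <- best$value
  out
}

# Semivariance between *distinct* locations: continuous in h with
# gamma(0+) = nugget, so coincident-but-distinct observations (snapped
# geocoding) contribute the nugget off the diagonal and keep the kriging
# system non-singular. The diagonal (a point with itself) is always 0.
variogram_gamma_plus <- function(h, model) {
  c0 <- model$nugget; c1 <- model$partial_sill; a <- model$range
  if (model$model == "exponential") {
    c0 + c1 * (1 - exp(-3 * h / a))
  } else {
    ifelse(h < a, c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3), c0 + c1)
  }
}

# Deterministic 0.1 m jitter applied to coincident points when a
# zero-nugget variogram would make the kriging system singular.
jitter_duplicates <- function(x, y, amount = 0.1) {
  key <- paste(x, y)
  dup <- duplicated(key)
  idx <- which(dup)
  ang <- 2 * pi * seq_along(idx) / max(1, length(idx))
  x[idx] <- x[idx] + amount * cos(ang)
  y[idx] <- y[idx] + amount * sin(ang)
  list(x = x, y = y, n_moved = length(idx))
}

#' Ordinary kriging onto a grid
#'
#' Predicts a surface from scattered observations by ordinary kriging: at
#' each cell the `max_neighbors` nearest observations get weights solving
#' the semivariance system with the unbiasedness constraint
#' `sum(lambda) = 1` (Lagrange multiplier), and the prediction is
#' `sum(lambda * v)`. With a zero nugget the predictor honors the data
#' exactly at observation locations. Coincident observations are
#' regularized by the nugget; with a zero nugget they are jittered by
#' 0.1 m (reported via a warning) or rejected, per `duplicates`.
#'
#' @param pts data frame with `x`, `y` and `value` (or `group`) columns.
#' @param grid prediction [make_grid()] grid.
#' @param model a [variogram_model()].
#' @param max_neighbors number of nearest observations per prediction
#'   (default 16).
#' @param duplicates `"jitter"` (default) or `"fail"`: handling of
#'   coincident points when the nugget is zero.
#' @return A continuous [smc_raster()] of predictions.
#' @export
ordinary_krige <- function(pts, grid, model, max_neighbors = 16,
                           duplicates = c("jitter", "fail")) {
  duplicates <- match.arg(duplicates)
  pts <- tibble::as_tibble(pts)
  v <- point_values(pts)
  x <- pts$x; y <- pts$y
  if (length(unique(paste(x, y))) < 2) stop_invalid("need at least two distinct points")
  if (model$nugget == 0 && anyDuplicated(paste(x, y))) {
    if (duplicates == "fail") {
      abort("coincident points with a zero-nugget variogram make the kriging system singular",
            class = "smcair_error_singular")
    }
    j <- jitter_duplicates(x, y)
    warn(sprintf("jittered %d coincident point(s) by 0.1 m (zero-nugget variogram)",
                 j$n_moved))
    x <- j$x; y <- j$y
  }
  n <- length(v)
  k <- min(max_neighbors, n)
  cx <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$y_max - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  pred <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  # cache per unique neighbor set: repeated sets share one factorization
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(grid$n_rows)) {
    dy2 <- (y - cy[i])^2
    for (j in seq_len(grid$n_cols)) {
      d2 <- (x - cx[j])^2 + dy2
      nb <- order(d2)[seq_len(k)]
      key <- paste(nb, collapse = ",")
      fac <- cache[[key]]
      if (is.null(fac)) {
        G <- variogram_gamma_plus(as.matrix(dist(cbind(x[nb], y[nb]))), model)
        diag(G) <- 0
        A <- rbind(cbind(G, 1), c(rep(1, k), 0))
        fac <- list(Ainv = tryCatch(solve(A), error = function(e) NULL), nb = nb)
        cache[[key]] <- fac
      }
      if (is.null(fac$Ainv)) {
        abort("singular kriging system (coincident neighbors); use a positive nugget or jitter",
              class = "smcair_error_singular")
      }
      g0 <- c(variogram_gamma_plus(sqrt(d2[nb]), model), 1)
      lambda <- (fac$Ainv %*% g0)[seq_len(k)]
      pred[i, j] <- sum(lambda * v[nb])
    }
  }
  smc_raster(pred, grid, kind = "continuous")
}

#' Kriged odds-ratio surface
#'
#' Turns a kriged case-probability surface into an odds-ratio surface
#' relative to the study-wide odds: with `p` the local kriged probability
#' that a residence is a case, `OR = (p / (1 - p)) / (n_cases / n_controls)`,
#' so `OR = 1` means no local excess of cases and `OR > 1` a local excess.
#' Probabilities are clipped to `[eps, 1 - eps]` first, keeping the odds
#' finite.
#'
#' @param p_hat continuous [smc_raster()] of kriged case probabilities.
#' @param n_cases,n_controls study-wide group totals.
#' @param eps clipping bound (default 1e-6).
#' @return An `or_surface` list: `p_hat` (clipped), `or` (raster),
#'   `baseline_odds`.
#' @export
odds_ratio_surface <- function(p_hat, n_cases, n_controls, eps = 1e-6) {
  if (n_controls <= 0) stop_invalid("`n_controls` must be positive")
  if (n_cases <= 0) stop_invalid("`n_cases` must be positive")
  baseline <- n_cases / n_controls
  ok <- raster_mask(p_hat)
  p <- p_hat$values
  p[ok] <- pmin(1 - eps, pmax(eps, p[ok]))
  or <- p
  or[ok] <- (p[ok] / (1 - p[ok])) / baseline
  structure(
    list(
      p_hat = smc_raster(p, p_hat$grid, kind = "continuous", nodata = p_hat$nodata),
      or = smc_raster(or, p_hat$grid, kind = "continuous", nodata = p_hat$nodata),
      baseline_odds = baseline
    ),
    class = "or_surface"
  )
}

#' @export
print.or_surface <- function(x, ...) {
  cat(sprintf("<or_surface> baseline odds %.4f\n  p_hat: ", x$baseline_odds))
  print(x$p_hat)
  cat("  OR:    "); print(x$or)
  invisible(x)
}

#' Indicator kriging of the case-control marks, end to end
#'
#' Convenience wrapper for the epidemiological surface: computes the
#' empirical semivariogram of the case indicator, fits the variogram
#' model, kriges the indicator onto the grid and derives the odds-ratio
#' surface against study-wide odds.
#'
#' @param residences residence tibble (`x`, `y`, `group`).
#' @param grid prediction grid.
#' @param model variogram family (default exponential) or a ready
#'   [variogram_model()] to skip fitting.
#' @param max_neighbors kriging neighborhood size (default 16).
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @return A list: `variogram` (fitted model), `empirical`, `surface`
#'   (an `or_surface`).
#' @export
krige_odds_ratio <- function(residences, grid, model = "exponential",
                             max_neighbors = 16, n_bins = 15, max_lag = NULL) {
  emp <- empirical_variogram(residences, n_bins = n_bins, max_lag = max_lag)
  vg <- if (inherits(model, "variogram_model")) model else fit_variogram(emp, model)
  p_hat <- ordinary_krige(residences, grid, vg, max_neighbors = max_neighbors)
  n_cases <- sum(residences$group == "case")
  n_controls <- sum(residences$group == "control")
  list(variogram = vg, empirical = emp,
       surface = odds_ratio_surface(p_hat, n_cases, n_controls))
}
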