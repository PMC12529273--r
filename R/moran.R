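#' Distance-band spatial weights
#'
#' Builds row-standardized spatial weights over a point set: `j` is a
#' neighbor of `i` iff `i != j` and `dist(i, j) <= band`. Coincident
#' points (records sharing a postal centroid after coarse geocoding) are
#' mutual neighbors at distance zero; a point is only ever excluded as its
#' own neighbor. Each non-isolated row is standardized to sum 1; points
#' with no neighbor within the band are flagged isolated, not dropped.
#' The epidemiological default band is 4 km, the distance taken as the
#' maximum reach of pollutant emission from an industrial unit.
#'
#' @param pts data frame with columns `x`, `y` (meters).
#' @param band neighborhood distance in meters (default 4000).
#' @return A `spatial_weights` object: per-point neighbor index lists,
#'   row-standardized weights, the band, and the coordinates.
#' @export
distance_band_weights <- function(pts, band = 4000) {
  pts <- tibble::as_tibble(pts)
  n <- nrow(pts)
  if (n < 2) stop_invalid("need at least two points")
  if (!is.numeric(band) || band <= 0) stop_invalid("`band` must be positive meters")
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- unname(which(d[i, ] <= band))
    nb <- nb[nb != i]
    neighbors[[i]] <- nb
    weights[[i]] <- if (length(nb)) rep(1 / length(nb), length(nb)) else numeric()
  }
  structure(
    list(neighbors = neighbors, weights = weights, band = band,
         n = n, coords = cbind(x = pts$x, y = pts$y)),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat(sprintf(
    "<spatial_weights> %d points, band %g m, avg %.1f neighbors, %d isolated\n",
    x$n, x$band, mean(k), sum(k == 0)
  ))
  invisible(x)
}

# All permutations of seq_len(n), as a matrix with one permutation per row.
# Only used by the exhaustive ("exact") permutation mode on tiny inputs.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

#' Local Moran's I cluster and outlier detection
#'
#' Computes Anselin's Local Moran's I per point for a numeric variable
#' (here the binary case indicator: 1 = case, 0 = control) under
#' distance-band weights, with conditional permutation inference: for each
#' point the remaining values are permuted among the other positions while
#' the point's own value is held fixed. With centered values
#' `z_i = x_i - mean(x)` and `m2 = sum(z^2) / n`, the statistic is
#' `I_i = (z_i / m2) * sum_j w_ij z_j`. Significant points are labelled by
#' quadrant: `HH` (high value, high-value neighborhood — a local excess of
#' cases), `LL`, `HL`, `LH`; non-significant points `ns`; points without
#' neighbors `isolated`.
#'
#' The default p-value is two-sided (the smaller permutation tail, folded:
#' `min(1, 2 * min(p_upper, p_lower))`), so labelling at `alpha` holds the
#' null labelling rate near `alpha`. `alternative = "greater"` or
#' `"less"` gives the one-tailed permutation p-value
#' `(1 + #{perm I beyond observed}) / (1 + n_perm)` directly.
#'
#' @param pts data frame with columns `x`, `y` and either `group`
#'   (`"case"`/`"control"`) or a numeric `value` column.
#' @param weights a [distance_band_weights()] object (built from `pts` if
#'   omitted).
#' @param band neighborhood distance used when `weights` is omitted.
#' @param n_perm number of conditional permutations (>= 99), or `"exact"`
#'   to enumerate all permutations (only feasible for about 8 points or
#'   fewer).
#' @param alpha significance level for labelling (default 0.05).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param seed optional seed pinned before permutation.
#' @return A `local_moran` tibble, one row per point: `id`, `value`,
#'   `lag` (spatially lagged centered value), `I`, `z_score`
#'   (permutation z), `p_value`, `label`.
#' @export
local_morans_i <- function(pts, weights = NULL, band = 4000, n_perm = 999,
                           alpha = 0.05,
                           alternative = c("two.sided", "greater", "less"),
                           seed = NULL) {
  alternative <- match.arg(alternative)
  pts <- tibble::as_tibble(pts)
  x <- if ("value" %in% names(pts)) {
    as.numeric(pts$value)
  } else if ("group" %in% names(pts)) {
    as.numeric(pts$group == "case")
  } else {
    stop_invalid("`pts` needs a `value` or `group` column")
  }
  n <- length(x)
  if (length(unique(x)) < 2) {
    stop_degenerate("values are constant: zero variance, Local Moran's I undefined")
  }
  if (is.null(weights)) weights <- distance_band_weights(pts, band)
  if (weights$n != n) stop_invalid("`weights` were built for a different point set")
  exact <- identical(n_perm, "exact")
  if (!exact && n_perm < 99) stop_invalid("`n_perm` must be at least 99 (or \"exact\")")

  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) {
    sum(weights$weights[[i]] * z[weights$neighbors[[i]]])
  }, numeric(1))
  iso <- lengths(weights$neighbors) == 0
  I <- (z / m2) * lag
  I[iso] <- NA_real_

  if (exact) {
    if (n > 9) stop_invalid("exact enumeration is limited to 9 points")
    perms <- all_permutations(n - 1L)
    n_sim <- nrow(perms)
    stat <- matrix(NA_real_, n, 4)
    for (i in seq_len(n)) {
      if (iso[i]) next
      others <- z[-i]
      nb <- weights$neighbors[[i]]
      # neighbour positions within the reduced vector (index shift past i)
      slots <- ifelse(nb > i, nb - 1L, nb)
      w <- weights$weights[[i]]
      lag_perm <- perms[, slots, drop = FALSE]
      lag_perm[] <- others[lag_perm]
      I_perm <- (z[i] / m2) * as.vector(lag_perm %*% w)
      stat[i, ] <- c(mean(I_perm), sd(I_perm),
                     sum(I_perm >= I[i] - 1e-12), sum(I_perm <= I[i] + 1e-12))
    }
    # the observed assignment is one of the enumerated permutations
    p_upper <- stat[, 3] / n_sim
    p_lower <- stat[, 4] / n_sim
  } else {
    if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
    nb0 <- lapply(weights$neighbors, function(v) as.integer(v - 1L))
    stat <- local_moran_perm_cpp(z, nb0, weights$weights, ifelse(iso, 0, I), m2,
                                 as.integer(n_perm))
    n_sim <- n_perm
    p_upper <- (1 + stat[, 3]) / (1 + n_sim)
    p_lower <- (1 + stat[, 4]) / (1 + n_sim)
  }

  p <- switch(alternative,
    greater = p_upper,
    less = p_lower,
    two.sided = pmin(1, 2 * pmin(p_upper, p_lower))
  )
  p[iso] <- NA_real_
  z_score <- (I - stat[, 1]) / ifelse(stat[, 2] > 0, stat[, 2], NA_real_)

  label <- rep("ns", n)
  sig <- !iso & !is.na(p) & p <= alpha
  label[sig & z > 0 & lag > 0] <- "HH"
  label[sig & z < 0 & lag < 0] <- "LL"
  label[sig & z > 0 & lag < 0] <- "HL"
  label[sig & z < 0 & lag > 0] <- "LH"
  label[iso] <- "isolated"

  marks <- x  # the analysed variable; `x` would be shadowed by the coordinate column
  out <- tibble::tibble(
    id = if ("id" %in% names(pts)) pts$id else as.character(seq_len(n)),
    x = pts$x, y = pts$y,
    value = marks, lag = lag, I = I,
    z_score = z_score, p_value = p, label = label
  )
  attr(out, "alpha") <- alpha
  attr(out, "alternative") <- alternative
  attr(out, "n_perm") <- if (exact) "exact" else n_perm
  attr(out, "band") <- weights$band
  class(out) <- c("local_moran", class(out))
  out
}

#' @export
tidy.local_moran <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.local_moran <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_significant = sum(x$label %in% c("HH", "LL", "HL", "LH")),
    n_hh = sum(x$label == "HH"),
    n_isolated = sum(x$label == "isolated"),
    global_i = mean(x$I, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    band = attr(x, "band")
  )
}

#' @export
autoplot.local_moran <- function(object, ...) {
  pal <- c(HH = "#d7191c", LL = "#2c7bb6", HL = "#fdae61", LH = "#abd9e9",
           ns = "grey70", isolated = "grey40")
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$x, y = .data$y, color = .data$label)) +
    ggplot2::geom_point(size = 1.8, alpha = 0.85) +
    ggplot2::scale_color_manual(values = pal, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", color = "cluster type",
                  title = "Local Moran's I cluster and outlier labels") +
    ggplot2::theme_minimal()
}
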