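#' Weighted linear combination of factor score rasters
#'
#' Combines the factor score rasters x_i into the continuous
#' susceptibility index `S = sum_i w_i * x_i`, cell-wise. Because the
#' weights are non-negative and sum to 1, S is a convex combination of the
#' factor scores and stays inside \[1, 3\]. Nodata in any factor propagates
#' to S.
#'
#' @param factors named list of score/class [smc_raster()]s sharing one
#'   grid.
#' @param weights named numeric vector covering exactly the factors, with
#'   non-negative entries summing to 1 (within 1e-9).
#' @return A continuous [smc_raster()] holding S.
#' @examples
#' g <- make_grid(c(0, 0, 20, 20), 10)
#' f <- list(a = smc_raster(matrix(3, 2, 2), g, "score"),
#'           b = smc_raster(matrix(1, 2, 2), g, "score"))
#' wlc(f, c(a = 0.75, b = 0.25))$values
#' @export
wlc <- function(factors, weights) {
  if (!length(factors) || is.null(names(factors)) || any(names(factors) == "")) {
    stop_invalid("`factors` must be a non-empty named list of rasters")
  }
  if (!setequal(names(weights), names(factors))) {
    stop_invalid(sprintf(
      "weights must cover exactly the provided factors; got weights for {%s}, factors {%s}",
      paste(names(weights), collapse = ", "), paste(names(factors), collapse = ", ")
    ))
  }
  if (any(weights < 0)) stop_invalid("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_invalid(sprintf("weights must sum to 1 (got %.6f)", sum(weights)))
  }
  grid <- factors[[1]]$grid
  for (nm in names(factors)) {
    if (!grid_equal(factors[[nm]]$grid, grid)) {
      abort(sprintf("factor \"%s\" is not aligned to the common grid", nm),
            class = "smcair_error_alignment")
    }
  }
  s <- matrix(0, grid$n_rows, grid$n_cols)
  ok <- matrix(TRUE, grid$n_rows, grid$n_cols)
  for (nm in names(factors)) {
    f <- factors[[nm]]
    m <- raster_mask(f)
    ok <- ok & m
    s <- s + weights[[nm]] * ifelse(m, f$values, 0)
  }
  s[!ok] <- -9999
  smc_raster(s, grid, kind = "continuous", nodata = -9999)
}

#' Classify the susceptibility index into low/moderate/high
#'
#' Cuts the continuous index S (range \[1, 3\]) into three classes. The
#' default `equal_interval` rule is data-independent: thirds of the
#' theoretical range, `[1, 5/3)` low, `[5/3, 7/3)` moderate, `[7/3, 3]`
#' high (the top class closed at 3, mirroring factor classing).
#' `quantile` cuts at the tertiles of the non-nodata cells instead.
#'
#' @param s the continuous index raster from [wlc()], values in \[1, 3\].
#' @param method `"equal_interval"` (default) or `"quantile"`.
#' @return A class [smc_raster()] (1 = low, 2 = moderate, 3 = high).
#' @export
classify_susceptibility <- function(s, method = c("equal_interval", "quantile")) {
  method <- match.arg(method)
  ok <- raster_mask(s)
  v <- s$values
  if (any(v[ok] < 1 - 1e-9) || any(v[ok] > 3 + 1e-9)) {
    stop_invalid("susceptibility index values must lie in [1, 3]")
  }
  breaks <- if (method == "equal_interval") {
    c(5 / 3, 7 / 3)
  } else {
    unname(stats::quantile(v[ok], c(1 / 3, 2 / 3), names = FALSE))
  }
  cls <- matrix(0, nrow(v), ncol(v))
  cls[ok & v < breaks[1]] <- 1
  cls[ok & v >= breaks[1] & v < breaks[2]] <- 2
  cls[ok & v >= breaks[2]] <- 3
  smc_raster(cls, s$grid, kind = "class")
}

#' Build the full susceptibility map from factor rasters
#'
#' Convenience wrapper running [wlc()] then [classify_susceptibility()],
#' recording the configuration used.
#'
#' @inheritParams wlc
#' @inheritParams classify_susceptibility
#' @return A list with `index` (continuous S raster), `classes` (class
#'   raster) and `config` (weights and class method), class
#'   `susceptibility_map`.
#' @export
susceptibility_map <- function(factors, weights,
                               method = c("equal_interval", "quantile")) {
  method <- match.arg(method)
  s <- wlc(factors, weights)
  structure(
    list(index = s,
         classes = classify_susceptibility(s, method),
         config = list(weights = as.list(weights), class_method = method)),
    class = "susceptibility_map"
  )
}

#' @export
print.susceptibility_map <- function(x, ...) {
  cat("<susceptibility_map>\n  index:   "); print(x$index)
  cat("  classes: "); print(x$classes)
  w <- unlist(x$config$weights)
  cat(sprintf("  weights: %s; classing: %s\n",
              paste(sprintf("%s=%.2f", names(w), w), collapse = ", "),
              x$config$class_method))
  invisible(x)
}
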