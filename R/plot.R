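#' Plot a raster layer
#'
#' @param object an [smc_raster()].
#' @param ... unused.
#' @return A ggplot object (`geom_raster` of cell values; class rasters
#'   are drawn with an ordinal low/moderate/high fill).
#' @export
autoplot.smc_raster <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (object$kind %in% c("class", "binary")) {
    df$class <- factor(df$value, levels = 1:3, labels = c("low", "moderate", "high"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_manual(
        values = c(low = "#1a9641", moderate = "#fdae61", high = "#d7191c"),
        na.value = "grey90", drop = FALSE
      )
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot an empirical semivariogram with an optional fitted model
#'
#' @param empirical tibble from [empirical_variogram()].
#' @param model optional [variogram_model()] drawn as a curve.
#' @return A ggplot object.
#' @export
plot_variogram <- function(empirical, model = NULL) {
  p <- ggplot2::ggplot(empirical, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "lag (m)", y = "semivariance", size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    hh <- seq(0, max(empirical$lag), length.out = 200)
    fit <- tibble::tibble(lag = hh, gamma = variogram_gamma(hh, model))
    p <- p + ggplot2::geom_line(data = fit, color = "#d7191c")
  }
  p
}

#' @export
autoplot.susceptibility_map <- function(object, ...) {
  autoplot(object$classes) +
    ggplot2::labs(fill = "susceptibility",
                  title = "Air-pollution susceptibility classes")
}

#' @export
autoplot.or_surface <- function(object, ...) {
  autoplot(object$or) +
    ggplot2::labs(fill = "odds ratio",
                  title = "Kriged case-control odds-ratio surface")
}
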