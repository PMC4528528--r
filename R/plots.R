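#' Heat-map and profile plots
#'
#' `autoplot()` methods for the three result types. Density maps render as
#' occupancy rasters. Significance maps use a nonlinear p-value scale
#' (signed -log10 p) with a diverging palette, orange/blue for
#' occupancy-vs-baseline tests and pink/green for group comparisons, so that
#' direction is read from colour as in the customary figures.
#'
#' @param object A `density_map`, `significance_map` or `distance_profile`.
#' @param cap Cap on -log10(p) for display (default 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-shoalwatch
NULL

#' @rdname autoplot-shoalwatch
#' @export
autoplot.density_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "visit\nfraction") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-shoalwatch
#' @export
autoplot.significance_map <- function(object, cap = 4, ...) {
  kind <- attr(object, "test_kind")
  pal <- if (identical(kind, "occupancy_signed_rank")) {
    c("#2166ac", "#f7f7f7", "#e08214") # blue / orange
  } else {
    c("#1b7837", "#f7f7f7", "#c51b7d") # green / pink
  }
  df <- object
  df$score <- df$direction * pmin(-log10(pmax(df$p, 10^(-cap))), cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = pal[1], mid = pal[2], high = pal[3],
                                  limits = c(-cap, cap),
                                  name = "signed\n-log10 p") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", subtitle = kind) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-shoalwatch
#' @export
autoplot.distance_profile <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "relative"))) {
    "relative density (observed - uniform null)"
  } else {
    "density"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_centre)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "distance to object (cm)", y = ylab) +
    ggplot2::theme_minimal()
}
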