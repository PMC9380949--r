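#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_line
#'   geom_point geom_errorbar geom_hline coord_polar facet_wrap labs
#'   scale_fill_viridis_c scale_fill_viridis_d theme_minimal
#' @export
ggplot2::autoplot

#' Current-rose plot
#'
#' Stacked polar frequency plot of the [rose_table()] cells: one wedge per
#' direction sector, stacked by speed class, faceted by site.
#'
#' @param object A `reef_rose_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reef_rose_table
#' @export
autoplot.reef_rose_table <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$dir_bin_center), y = .data$percent,
                     fill = .data$speed_bin)) +
    geom_col(width = 1, colour = "grey30", linewidth = 0.1) +
    coord_polar(start = -pi / length(unique(object$dir_bin_center))) +
    facet_wrap(~site_id) +
    scale_fill_viridis_d(name = "speed (m/s)") +
    labs(x = "heading-to direction (deg from N)", y = "% of hourly means") +
    theme_minimal()
}

#' Polar temperature plot
#'
#' Direction x speed cells coloured by mean temperature, faceted by site.
#'
#' @param object A `reef_polar_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reef_polar_table
#' @export
autoplot.reef_polar_table <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$dir_bin_center), y = .data$speed_bin,
                     fill = .data$mean_temp)) +
    geom_tile() +
    coord_polar() +
    facet_wrap(~site_id) +
    scale_fill_viridis_c(name = "temp (degC)", option = "plasma") +
    labs(x = "heading-to direction (deg from N)", y = "speed class") +
    theme_minimal()
}

#' Paired in-situ / SST series plot
#'
#' Daily in-situ means and the expanded satellite SST series on one time
#' axis, showing the systematic offset.
#'
#' @param object A `reef_sst_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reef_sst_comparison
#' @export
autoplot.reef_sst_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs, c("insitu", "sst"),
                              names_to = "series", values_to = "temp_c")
  ggplot(long, aes(x = .data$date, y = .data$temp_c,
                   colour = .data$series)) +
    geom_line() +
    labs(x = NULL, y = "temperature (degC)",
         title = sprintf("In-situ minus SST offset: %.2f degC", object$offset)) +
    theme_minimal()
}

#' Marginal means and contrasts plot for a group model
#'
#' Two-panel style summary: group marginal means with 95% CIs (left facet
#' data) are returned as one plot here; combine with
#' [pairwise_contrasts()] for the contrast panel.
#'
#' @param object A `reef_group_model`.
#' @param ... Unused.
#' @return A ggplot of response-scale marginal means with 95% CIs.
#' @method autoplot reef_group_model
#' @export
autoplot.reef_group_model <- function(object, ...) {
  mm <- marginal_means(object)
  ggplot(mm, aes(x = .data$group, y = .data$estimate)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.15) +
    labs(x = NULL, y = object$spec$response,
         title = sprintf("Estimated marginal means (%s)", object$spec$family)) +
    theme_minimal()
}

#' Contrast interval plot
#'
#' Tukey-adjusted pairwise contrast estimates with a zero reference line.
#'
#' @param contrasts Output of [pairwise_contrasts()].
#' @return A ggplot.
#' @export
plot_contrasts <- function(contrasts) {
  ggplot(contrasts, aes(x = .data$estimate, y = .data$contrast)) +
    geom_point(size = 2) +
    geom_errorbar(aes(xmin = .data$lower, xmax = .data$upper),
                  width = 0.15, orientation = "y") +
    geom_hline(yintercept = 0, linetype = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "contrast (response scale)", y = NULL) +
    theme_minimal()
}
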