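#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a density map channel
#'
#' Raster plot of one concentration plane, in mg/ml.
#'
#' @param object A [density_map()].
#' @param channel `"protein"`, `"lipid"`, `"water"` or `"dry_mass"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, channel = "protein", ...) {
  plane <- if (channel == "dry_mass") dry_mass_density(object) else object[[channel]]
  df <- tidyr::expand_grid(
    row = seq_len(nrow(plane)),
    col = seq_len(ncol(plane))
  )
  df$value <- 1000 * as.numeric(t(plane))[(df$row - 1) * ncol(plane) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      fill = sprintf("%s\n(mg/ml)", channel)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Hoechst gating result
#'
#' Histogram of G1-normalised Hoechst with the stage gates.
#'
#' @param object A `hoechst_gating` tibble from [hoechst_gates()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hoechst_gating <- function(object, bins = 60, ...) {
  gates <- attr(object, "gates")
  ggplot2::ggplot(object, ggplot2::aes(.data$hoechst_norm)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = gates, linetype = "dashed") +
    ggplot2::labs(
      x = "Hoechst intensity (normalised to G1 peak)",
      y = "cells"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an EdU gating result
#'
#' Scatter of log EdU intensity vs normalised Hoechst with the positivity
#' threshold.
#'
#' @param object An `edu_gating` tibble from [edu_gate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edu_gating <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$hoechst_norm, .data$log_edu, colour = .data$edu_positive)
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "Hoechst (normalised)", y = "log EdU intensity",
                  colour = "EdU+") +
    ggplot2::theme_minimal()
}

#' Compartment density distributions of a population
#'
#' Faceted histograms of the measured compartment densities (mg/ml).
#'
#' @param pop Population tibble (e.g. `run_pipeline()$population`).
#' @param channels Density columns (g/ml) to plot.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_population_densities <- function(pop,
                                      channels = c("cyto_protein", "cyto_lipid",
                                                   "nup_protein", "nul_protein"),
                                      bins = 40) {
  long <- tidyr::pivot_longer(
    pop[, channels],
    cols = dplyr::all_of(channels),
    names_to = "channel", values_to = "value"
  )
  long$value <- 1000 * long$value
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = "density (mg/ml)", y = "cells") +
    ggplot2::theme_minimal()
}
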