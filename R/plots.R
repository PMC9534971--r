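#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

wm_class_palette <- c(
  gap = "black", island = "#9E1FEF", network = "#00CC33",
  outside = "grey40", ec_total = "#E6B800"
)

#' Plot a region label map
#'
#' False-color rendering with the standard palette: gap black, island
#' purple, network green.
#'
#' @param object a `region_labelmap`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot region_labelmap
#' @export
autoplot.region_labelmap <- function(object, ...) {
  m <- as_mat(object)
  df <- tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    class = factor(as.vector(class_name_of(m)),
      levels = c("gap", "island", "network", "outside")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = wm_class_palette, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Coverage-fraction bar chart
#'
#' Percentage of area covered by islands, networks and total EC per zone,
#' the whole-well coverage layout of the assay.
#'
#' @param coverage output of [coverage_fractions()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  df <- coverage[coverage$region_class != "gap" & coverage$zone != "well", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$zone, 100 * .data$area_fraction,
    fill = .data$region_class
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = wm_class_palette) +
    ggplot2::labs(x = NULL, y = "area covered (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Proliferation-by-region bar chart
#'
#' @param prolif output of [proliferation_by_region()].
#' @return A ggplot object.
#' @export
plot_proliferation <- function(prolif) {
  ggplot2::ggplot(
    prolif,
    ggplot2::aes(.data$region_class, .data$smc_prolif_pct, fill = .data$region_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~zone) +
    ggplot2::scale_fill_manual(values = wm_class_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "proliferative SMCs (%)") +
    ggplot2::theme_minimal()
}

#' Radial profile plot
#'
#' SMC and fibronectin intensity (0-255 display scale) and the Fn/SMC ratio
#' from the rim (left) to the well center (right), with region occupancy
#' as a band underneath.
#'
#' @param profiles output of [radial_profiles()].
#' @return A ggplot object.
#' @export
plot_radial_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles[, c("bin", "smc_0_255", "fn_0_255")],
    -"bin",
    names_to = "channel", values_to = "intensity"
  )
  ratio_scale <- 255 / max(profiles$fn_over_smc, na.rm = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$intensity,
    color = .data$channel
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(
      data = profiles,
      ggplot2::aes(.data$bin, .data$fn_over_smc * ratio_scale),
      color = "steelblue", linetype = 2, inherit.aes = FALSE, na.rm = TRUE
    ) +
    ggplot2::scale_color_manual(
      values = c(smc_0_255 = "firebrick", fn_0_255 = "grey30"),
      labels = c(smc_0_255 = "SMC (cell tracker)", fn_0_255 = "plasma Fn")
    ) +
    ggplot2::labs(
      x = "radial bin (rim to center)", y = "intensity (0-255)",
      color = NULL,
      caption = "dashed: Fn/SMC ratio (rescaled)"
    ) +
    ggplot2::theme_minimal()
}

#' Layering-index bar chart
#'
#' @param layering output of [smc_layering_index()].
#' @return A ggplot object.
#' @export
plot_layering <- function(layering) {
  ggplot2::ggplot(
    layering,
    ggplot2::aes(.data$region_class, .data$smc_intensity_norm,
      fill = .data$region_class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~zone) +
    ggplot2::scale_fill_manual(values = wm_class_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "SMC intensity (island = 1)") +
    ggplot2::theme_minimal()
}
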