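#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   facet_wrap facet_grid labs scale_fill_viridis_c theme_minimal
NULL

#' Plot a reflectance map
#'
#' Raster of diffuse reflectance over the wavelength and spatial frequency
#' grid.
#'
#' @param object A `reflectance_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reflectance_map <- function(object, ...) {
  ggplot(object, aes(x = .data$fx_per_mm, y = .data$wavelength_nm,
                     fill = .data$rd)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(R[d])) +
    labs(x = expression(f[x] ~ (mm^-1)), y = "wavelength (nm)") +
    theme_minimal()
}

#' Plot a sensitivity curve
#'
#' @param object A `sensitivity_curve` (or several row-bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$fx_per_mm, y = .data$dRd_dp,
                     colour = .data$parameter_id)) +
    geom_line() +
    labs(x = expression(f[x] ~ (mm^-1)),
         y = expression(partialdiff * R[d] / partialdiff * p ~ (mm)),
         colour = NULL) +
    theme_minimal()
}

#' Plot recovered spectra of a staged inversion
#'
#' Final (and optionally per-stage) recovered absorption and reduced
#' scattering spectra for both layers, with the ground truth overlaid when
#' available.
#'
#' @param object An `sfd_inversion`.
#' @param truth Optional tibble (`wavelength_nm`, `layer`, `mua`, `musp`)
#'   as produced by [build_media()]/[simulate_phantom()].
#' @param stages Stage snapshots to show (default: final per property).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfd_inversion <- function(object, truth = NULL,
                                   stages = c(1L, 3L, 4L, 2L), ...) {
  sp <- tidy(object, stages = stages)
  # keep the latest stage per (layer, property)
  sp <- dplyr::slice_max(
    dplyr::group_by(sp, .data$wavelength_nm, .data$layer, .data$property),
    .data$stage, n = 1, with_ties = FALSE)
  p <- ggplot(sp, aes(x = .data$wavelength_nm, y = .data$value)) +
    geom_line(aes(colour = "recovered")) +
    facet_grid(.data$property ~ .data$layer, scales = "free_y") +
    labs(x = "wavelength (nm)", y = expression(mm^-1), colour = NULL) +
    theme_minimal()
  if (!is.null(truth)) {
    tr <- tidyr::pivot_longer(truth, c("mua", "musp"),
                              names_to = "property", values_to = "value")
    p <- p + geom_line(data = tr, aes(colour = "truth"), linetype = 2)
  }
  p
}

#' @rdname autoplot.reflectance_map
#' @param map A `reflectance_map`.
#' @export
plot_reflectance_map <- function(map, ...) autoplot.reflectance_map(map, ...)

#' @rdname autoplot.sensitivity_curve
#' @param curve A `sensitivity_curve`.
#' @export
plot_sensitivity <- function(curve, ...) autoplot.sensitivity_curve(curve, ...)
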