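#' Optical properties of a single layer
#'
#' Bundles the per-wavelength optical properties of one homogeneous layer:
#' absorption coefficient `mua` (mm^-1), reduced scattering coefficient `musp`
#' (mm^-1), single-scattering anisotropy `g` (mean cosine of the scattering
#' angle) and refractive index `n`.
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, mm^-1 (> 0).
#' @param g Single-scattering anisotropy, in [0, 1). Default 0.8, the usual
#'   soft-tissue value.
#' @param n Refractive index (>= 1). Default 1.4.
#' @return An object of class `optical_layer`.
#' @examples
#' optical_layer(mua = 0.01, musp = 1)
#' @export
optical_layer <- function(mua, musp, g = 0.8, n = 1.4) {
  for (v in list(mua, musp, g, n)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort("optical_layer fields must be finite scalars",
            class = "sfdlayers_input_error")
    }
  }
  if (mua < 0) abort("mua must be >= 0", class = "sfdlayers_input_error")
  if (musp <= 0) abort("musp must be > 0", class = "sfdlayers_input_error")
  if (g >= 1) {
    abort("g = 1 is a degenerate phase function (musp/(1-g) undefined)",
          class = "sfdlayers_degenerate_phase_error")
  }
  if (g < 0) abort("g must be in [0, 1)", class = "sfdlayers_input_error")
  if (n < 1) abort("n must be >= 1", class = "sfdlayers_input_error")
  structure(list(mua = mua, musp = musp, g = g, n = n),
            class = "optical_layer")
}

#' @export
print.optical_layer <- function(x, ...) {
  cat(sprintf("<optical_layer> mua=%g musp=%g mm^-1, g=%g, n=%g\n",
              x$mua, x$musp, x$g, x$n))
  invisible(x)
}

#' Derived transport quantities for a layer
#'
#' Computes the scattering coefficient `mus = musp / (1 - g)`, total
#' attenuation `mut = mua + mus`, transport mean free path
#' `lstar = 1 / (mua + musp)` (mm, the natural length scale of diffusive
#' transport) and single-scattering albedo `mus / mut`.
#'
#' @param layer An [optical_layer()].
#' @return A one-row tibble with columns `mus`, `mut`, `lstar`, `albedo`.
#' @examples
#' derive_transport(optical_layer(0.1, 1.0, g = 0.8))
#' @export
derive_transport <- function(layer) {
  stopifnot(inherits(layer, "optical_layer"))
  mus <- layer$musp / (1 - layer$g)
  mut <- layer$mua + mus
  tibble::tibble(
    mus = mus,
    mut = mut,
    lstar = 1 / (layer$mua + layer$musp),
    albedo = mus / mut
  )
}

#' Legendre moments of the Henyey-Greenstein phase function
#'
#' Moment l of the Henyey-Greenstein kernel with anisotropy `g` is `g^l`;
#' moment 0 is 1 (normalization). These moments are what the collision
#' operator of the spherical-harmonic solver consumes, so an alternative
#' phase function can be substituted by supplying its moments.
#'
#' @param g Anisotropy in [0, 1).
#' @param order Expansion order N; `order + 1` moments are returned.
#' @return Numeric vector `g^(0:order)`.
#' @examples
#' phase_moments(0.8, 9)
#' @export
phase_moments <- function(g, order) {
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1) {
    abort("g must be a scalar in [0, 1)", class = "sfdlayers_input_error")
  }
  g^(0:order)
}

#' A stack of layers with thicknesses
#'
#' Describes the layered medium: layers ordered top first, one thickness per
#' layer in mm with the last entry `Inf` (semi-infinite base), and the
#' refractive index of the ambient above the top surface. Interior interfaces
#' are treated as index-matched, so all layers must share one refractive
#' index.
#'
#' @param layers List of [optical_layer()] objects, top first.
#' @param thicknesses Numeric vector of thicknesses in mm; last must be `Inf`,
#'   all others finite and > 0.
#' @param n_ambient Refractive index above the top surface (default 1).
#' @return An object of class `layered_medium`.
#' @examples
#' layered_medium(
#'   list(optical_layer(0.01, 1.1), optical_layer(0.1, 1.0)),
#'   thicknesses = c(0.3, Inf)
#' )
#' @export
layered_medium <- function(layers, thicknesses, n_ambient = 1) {
  if (inherits(layers, "optical_layer")) layers <- list(layers)
  if (length(layers) < 1 || !all(vapply(layers, inherits, TRUE, "optical_layer"))) {
    abort("layers must be a non-empty list of optical_layer objects",
          class = "sfdlayers_input_error")
  }
  if (length(thicknesses) != length(layers)) {
    abort("need one thickness per layer", class = "sfdlayers_input_error")
  }
  L <- length(layers)
  if (!is.infinite(thicknesses[L])) {
    abort("the last layer must be semi-infinite (thickness = Inf)",
          class = "sfdlayers_input_error")
  }
  if (L > 1 && !all(is.finite(thicknesses[-L]) & thicknesses[-L] > 0)) {
    abort("all finite thicknesses must be > 0", class = "sfdlayers_input_error")
  }
  ns <- vapply(layers, `[[`, 0, "n")
  if (max(ns) - min(ns) > 1e-12) {
    abort("interior interfaces are index-matched: all layers must share one refractive index",
          class = "sfdlayers_input_error")
  }
  if (!is.numeric(n_ambient) || n_ambient < 1) {
    abort("n_ambient must be >= 1", class = "sfdlayers_input_error")
  }
  structure(list(layers = layers, thicknesses = as.numeric(thicknesses),
                 n_ambient = n_ambient),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> %d layer(s), n_ambient=%g\n",
              length(x$layers), x$n_ambient))
  for (i in seq_along(x$layers)) {
    li <- x$layers[[i]]
    cat(sprintf("  [%d] d=%g mm: mua=%g musp=%g g=%g n=%g\n",
                i, x$thicknesses[i], li$mua, li$musp, li$g, li$n))
  }
  invisible(x)
}

#' Solver configuration
#'
#' @param order Spherical-harmonic expansion order N (default 9); the
#'   per-layer system has `(order + 1)^2` coupled depth equations.
#' @param mode_floor Smallest eigenvalue magnitude treated as nonzero; also
#'   the absorption perturbation (mm^-1) applied in the degenerate
#'   `fx = 0, mua = 0` case to avoid a zero transport eigenvalue.
#' @return An object of class `shef_config`.
#' @export
shef_config <- function(order = 9, mode_floor = 1e-9) {
  if (!is.numeric(order) || length(order) != 1 || order < 1 ||
      order != round(order)) {
    abort("order must be an integer >= 1", class = "sfdlayers_input_error")
  }
  structure(list(order = as.integer(order), mode_floor = mode_floor),
            class = "shef_config")
}
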