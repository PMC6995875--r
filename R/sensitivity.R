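#' Spatial frequency-resolved reflectance sensitivity
#'
#' Computes the partial derivative of diffuse reflectance with respect to one
#' layer's absorption or reduced scattering coefficient, as a function of
#' spatial frequency, by central finite differences of the forward solver.
#' These curves are what motivates the frequency-band choices of the staged
#' inversion: absorption sensitivity concentrates at low fx, scattering
#' sensitivity peaks at an interior fx, and high frequencies weight the
#' superficial layer.
#'
#' The default relative step is 0.01 of the base value; when the base value
#' is below 0.01 mm^-1 (e.g. a nearly transparent layer's mua) an absolute
#' step of 1e-4 mm^-1 is used instead, so the difference never degenerates.
#'
#' @param medium A [layered_medium()].
#' @param layer Index of the perturbed layer (1 = top).
#' @param property `"mua"` or `"musp"`.
#' @param frequencies Spatial frequency grid, mm^-1 (default the instrument
#'   grid 0 to 0.5 by 0.01).
#' @param rel_step Relative perturbation in (0, 0.1].
#' @param config A [shef_config()].
#' @return A tibble of class `sensitivity_curve` with columns `fx_per_mm`,
#'   `dRd_dp` (units mm, i.e. per mm^-1) and `parameter_id`.
#' @examples
#' m <- layered_medium(
#'   list(optical_layer(0.01, 1), optical_layer(0.1, 1)), c(0.3, Inf))
#' sensitivity_curve(m, layer = 2, property = "musp",
#'                   frequencies = seq(0, 0.2, 0.02))
#' @export
sensitivity_curve <- function(medium, layer, property = c("mua", "musp"),
                              frequencies = seq(0, 0.5, by = 0.01),
                              rel_step = 0.01, config = shef_config()) {
  stopifnot(inherits(medium, "layered_medium"))
  property <- match.arg(property)
  if (!is.numeric(layer) || length(layer) != 1 ||
      layer < 1 || layer > length(medium$layers)) {
    abort("layer index out of range", class = "sfdlayers_input_error")
  }
  if (!is.numeric(rel_step) || rel_step <= 0 || rel_step > 0.1) {
    abort("rel_step must be in (0, 0.1]", class = "sfdlayers_input_error")
  }
  if (is.unsorted(frequencies)) {
    abort("frequencies must be sorted ascending", class = "sfdlayers_input_error")
  }
  p0 <- medium$layers[[layer]][[property]]
  h <- if (p0 < 1e-2) 1e-4 else rel_step * p0
  perturbed <- function(delta) {
    m2 <- medium
    m2$layers[[layer]][[property]] <- p0 + delta
    m2
  }
  up <- perturbed(h)
  dn <- perturbed(-h)
  vals <- vapply(frequencies, function(f) {
    v <- (solve_layered_reflectance(up, f, config) -
            solve_layered_reflectance(dn, f, config)) / (2 * h)
    if (!is.finite(v)) {
      abort(sprintf("non-finite sensitivity at fx = %g mm^-1", f),
            class = "sfdlayers_solver_error")
    }
    v
  }, 0)
  structure(
    tibble::tibble(fx_per_mm = as.numeric(frequencies), dRd_dp = vals,
                   parameter_id = sprintf("layer%d_%s", layer, property)),
    class = c("sensitivity_curve", class(tibble::tibble()))
  )
}

#' Frequency of peak sensitivity magnitude
#'
#' Grid frequency maximizing `|dRd_dp|`; ties break toward the lower
#' frequency.
#'
#' @param curve A `sensitivity_curve` (or any tibble with `fx_per_mm` and
#'   `dRd_dp`).
#' @return Scalar fx, mm^-1.
#' @export
peak_frequency <- function(curve) {
  if (nrow(curve) == 0) abort("empty curve", class = "sfdlayers_input_error")
  v <- abs(curve$dRd_dp)
  if (all(v == 0)) {
    abort("all-zero sensitivity curve has no defined peak",
          class = "sfdlayers_undefined_peak_error")
  }
  curve$fx_per_mm[which.max(v)]
}

#' Decade-decay frequency of a sensitivity curve
#'
#' Smallest grid frequency at which `|dRd_dp|` has fallen to `1/factor` of
#' its value at fx = 0. Invariant under uniform rescaling of the curve. If
#' the threshold is never crossed on the grid, returns `Inf` ("beyond grid").
#'
#' @param curve A `sensitivity_curve`; must include fx = 0.
#' @param factor Decay ratio (default 10, one decade).
#' @return Scalar fx, mm^-1, or `Inf`.
#' @export
decay_frequency <- function(curve, factor = 10) {
  i0 <- which(curve$fx_per_mm == 0)
  if (length(i0) != 1) {
    abort("curve must contain fx = 0 exactly once",
          class = "sfdlayers_input_error")
  }
  v0 <- abs(curve$dRd_dp[i0])
  if (v0 == 0) {
    abort("sensitivity at fx = 0 is zero; decay frequency undefined",
          class = "sfdlayers_input_error")
  }
  hit <- which(abs(curve$dRd_dp) <= v0 / factor)
  if (length(hit) == 0) return(Inf)
  curve$fx_per_mm[hit[1]]
}
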