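#' Power-law scattering spectrum
#'
#' The standard spectral model for tissue scattering,
#' `musp(lambda) = A * (lambda / lambda0)^(-b)`, with `A` the reduced
#' scattering coefficient at the reference wavelength `lambda0 = 750` nm.
#'
#' @param A Reduced scattering at `lambda0`, mm^-1 (> 0).
#' @param b Scattering power (dimensionless).
#' @param lambda0 Reference wavelength, nm.
#' @return Object of class `power_law_scattering`.
#' @examples
#' pl <- power_law_scattering(1.1, 1.3)
#' musp_at(pl, c(450, 750, 1000))
#' @export
power_law_scattering <- function(A, b, lambda0 = 750) {
  if (!is.numeric(A) || A <= 0) abort("A must be > 0", class = "sfdlayers_input_error")
  structure(list(A = A, b = b, lambda0 = lambda0),
            class = "power_law_scattering")
}

#' Evaluate a power-law scattering spectrum
#'
#' @param pl A [power_law_scattering()].
#' @param wavelengths Wavelengths, nm.
#' @return musp values, mm^-1.
#' @export
musp_at <- function(pl, wavelengths) {
  stopifnot(inherits(pl, "power_law_scattering"))
  pl$A * (wavelengths / pl$lambda0)^(-pl$b)
}

#' Sum-of-Gaussians absorption spectrum
#'
#' Parametric family used to emulate smooth multi-peak chromophore spectra:
#' a baseline plus Gaussian peaks (center nm, width nm as standard deviation,
#' height mm^-1).
#'
#' @param baseline Baseline absorption, mm^-1.
#' @param centers,widths,heights Equal-length vectors of peak parameters.
#' @return Object of class `absorption_peaks`.
#' @export
absorption_peaks <- function(baseline = 0, centers = numeric(0),
                             widths = numeric(0), heights = numeric(0)) {
  if (length(centers) != length(widths) || length(centers) != length(heights)) {
    abort("centers, widths, heights must have equal length",
          class = "sfdlayers_input_error")
  }
  if (baseline < 0 || any(heights < 0) || any(widths <= 0 & length(widths) > 0)) {
    abort("absorption peak parameters must be nonnegative (widths > 0)",
          class = "sfdlayers_input_error")
  }
  structure(list(baseline = baseline, centers = centers, widths = widths,
                 heights = heights),
            class = "absorption_peaks")
}

#' Evaluate a sum-of-Gaussians absorption spectrum
#'
#' @param ap An [absorption_peaks()].
#' @param wavelengths Wavelengths, nm.
#' @return mua values, mm^-1.
#' @export
mua_at <- function(ap, wavelengths) {
  stopifnot(inherits(ap, "absorption_peaks"))
  out <- rep(ap$baseline, length(wavelengths))
  for (i in seq_along(ap$centers)) {
    out <- out + ap$heights[i] *
      exp(-(wavelengths - ap$centers[i])^2 / (2 * ap$widths[i]^2))
  }
  out
}

#' Top-layer absorption presets
#'
#' `"naphthol"` emulates a naphthol-green-like top-layer dye: a strong blue
#' peak, a double hump in the 600-850 nm window with values in the 0.01-0.02
#' mm^-1 range, and a mild near-infrared rise. `"naphthol_high"` is a
#' high-absorption variant whose baseline alone keeps mua >= 0.075 mm^-1
#' across 600-800 nm (useful for studying the regime where superficial
#' absorption is recoverable) while staying within the 0.2 mm^-1 phantom
#' ceiling everywhere.
#'
#' @param preset `"naphthol"` or `"naphthol_high"`.
#' @return An [absorption_peaks()] object.
#' @export
top_absorption_preset <- function(preset = c("naphthol", "naphthol_high")) {
  preset <- match.arg(preset)
  switch(preset,
    naphthol = absorption_peaks(
      baseline = 0.005,
      centers = c(470, 660, 775, 960),
      widths  = c(45, 30, 40, 60),
      heights = c(0.10, 0.010, 0.012, 0.045)
    ),
    naphthol_high = absorption_peaks(
      baseline = 0.075,
      centers = c(470, 660, 775, 960),
      widths  = c(45, 35, 45, 60),
      heights = c(0.08, 0.035, 0.040, 0.030)
    )
  )
}

#' Hemoglobin-like bottom-layer absorption basis
#'
#' A smooth synthetic stand-in for a hemoglobin-dyed base layer's absorption
#' spectrum: Q-band-like peaks near 540/575 nm, a weak 760 nm feature, a
#' water-like rise beyond 900 nm and a blue edge. Values stay within the
#' 0.01-0.2 mm^-1 phantom range on 450-1000 nm. This is a synthetic basis
#' shape, not a literature hemoglobin spectrum.
#'
#' @param wavelengths Wavelengths, nm.
#' @return A `chromophore_basis` tibble (columns `wavelength_nm`,
#'   `mua_per_unit`).
#' @export
hemoglobin_like_basis <- function(wavelengths) {
  ap <- absorption_peaks(
    baseline = 0.01,
    centers = c(450, 540, 575, 760, 980),
    widths  = c(30, 18, 15, 30, 45),
    heights = c(0.12, 0.09, 0.085, 0.02, 0.05)
  )
  chromophore_basis(wavelengths, mua_at(ap, wavelengths))
}

#' Known bottom-layer absorption basis
#'
#' The staged inversion assumes the spectral shape of the bottom layer's
#' absorption is known a priori; the recovered quantity is the scalar
#' coefficient beta multiplying this shape.
#'
#' @param wavelengths Wavelengths, nm, sorted ascending, no duplicates.
#' @param shape Nonnegative absorption per unit coefficient, mm^-1.
#' @return A tibble of class `chromophore_basis`.
#' @export
chromophore_basis <- function(wavelengths, shape) {
  if (length(wavelengths) != length(shape)) {
    abort("wavelengths and shape must have equal length",
          class = "sfdlayers_input_error")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    abort("basis wavelengths must be strictly ascending",
          class = "sfdlayers_input_error")
  }
  if (any(shape < 0)) {
    abort("basis shape must be nonnegative", class = "sfdlayers_input_error")
  }
  structure(tibble::tibble(wavelength_nm = as.numeric(wavelengths),
                           mua_per_unit = as.numeric(shape)),
            class = c("chromophore_basis", class(tibble::tibble())))
}

# Evaluate a basis on a requested grid; exact match required (the basis must
# cover the analysis grid).
basis_on_grid <- function(basis, wavelengths, context = "basis") {
  i <- match(round(wavelengths, 9), round(basis$wavelength_nm, 9))
  if (anyNA(i)) {
    abort(sprintf("%s does not cover wavelength(s) %s nm", context,
                  paste(utils::head(wavelengths[is.na(i)], 3), collapse = ", ")),
          class = "sfdlayers_input_error")
  }
  basis$mua_per_unit[i]
}

#' Two-layer phantom specification
#'
#' Describes a synthetic two-layer phantom in the style of layered
#' PDMS tissue phantoms: a thin top layer (power-law scattering plus a
#' multi-peak dye-like absorption spectrum) over a semi-infinite base
#' (power-law scattering plus `beta` times a known absorption basis shape).
#'
#' Spectra outside the phantom property ranges (mua 0.01-0.2 mm^-1,
#' musp 0.5-1.3 mm^-1) trigger a warning, not an error, when media are built.
#'
#' @param top_scattering,bottom_scattering [power_law_scattering()] objects.
#' @param top_absorption An [absorption_peaks()] object (or preset name).
#' @param beta Scalar coefficient of the bottom basis (>= 0).
#' @param basis A `chromophore_basis`, or `NULL` to use
#'   [hemoglobin_like_basis()] on the analysis grid.
#' @param thickness_mm Top layer thickness, mm (0.09 or 0.3 in the phantom
#'   study designs).
#' @param n Refractive index of both layers. @param n_ambient Ambient index.
#' @param g Single-scattering anisotropy of both layers.
#' @return Object of class `phantom_spec`.
#' @examples
#' phantom_spec()
#' @export
phantom_spec <- function(top_scattering = power_law_scattering(1.1, 1.3),
                         top_absorption = top_absorption_preset("naphthol"),
                         bottom_scattering = power_law_scattering(1.0, 1.2),
                         beta = 1,
                         basis = NULL,
                         thickness_mm = 0.3,
                         n = 1.4, n_ambient = 1, g = 0.8) {
  if (is.character(top_absorption)) {
    top_absorption <- top_absorption_preset(top_absorption)
  }
  stopifnot(inherits(top_scattering, "power_law_scattering"),
            inherits(bottom_scattering, "power_law_scattering"),
            inherits(top_absorption, "absorption_peaks"))
  if (beta < 0) abort("beta must be >= 0", class = "sfdlayers_input_error")
  if (thickness_mm <= 0) abort("thickness must be > 0", class = "sfdlayers_input_error")
  structure(list(top_scattering = top_scattering,
                 top_absorption = top_absorption,
                 bottom_scattering = bottom_scattering,
                 beta = beta, basis = basis, thickness_mm = thickness_mm,
                 n = n, n_ambient = n_ambient, g = g),
            class = "phantom_spec")
}

#' The 32-wavelength analysis grid
#'
#' Evenly spaced wavelengths spanning 450 to 1000 nm, endpoints included.
#'
#' @param n Number of wavelengths (default 32).
#' @return Numeric vector, nm.
#' @export
analysis_wavelengths <- function(n = 32) seq(450, 1000, length.out = n)

#' Build per-wavelength layered media from a phantom spec
#'
#' Deterministically expands a [phantom_spec()] into one [layered_medium()]
#' per wavelength, and attaches the ground-truth property spectra (for
#' scoring recovery) as the `truth` attribute.
#'
#' @param spec A [phantom_spec()].
#' @param wavelengths Wavelength grid, nm, within 450-1000 nm.
#' @return List of media with attributes `wavelengths`, `truth` (tibble with
#'   columns `wavelength_nm`, `layer`, `mua`, `musp`) and `basis`.
#' @export
build_media <- function(spec, wavelengths = analysis_wavelengths()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(wavelengths < 450 | wavelengths > 1000)) {
    abort("wavelength grid must lie within 450-1000 nm",
          class = "sfdlayers_input_error")
  }
  basis <- spec$basis %||% hemoglobin_like_basis(wavelengths)
  mua_t <- mua_at(spec$top_absorption, wavelengths)
  mua_b <- spec$beta * basis_on_grid(basis, wavelengths, "bottom-layer basis")
  musp_t <- musp_at(spec$top_scattering, wavelengths)
  musp_b <- musp_at(spec$bottom_scattering, wavelengths)

  rng_warn <- function(x, lo, hi, what) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) {
      warn(sprintf("%s leaves the phantom range [%g, %g] mm^-1 (span %.3g-%.3g)",
                   what, lo, hi, min(x), max(x)),
           class = "sfdlayers_range_warning")
    }
  }
  rng_warn(mua_t, 0.01, 0.2, "top-layer mua")
  rng_warn(mua_b, 0.01, 0.2, "bottom-layer mua")
  rng_warn(musp_t, 0.5, 1.3, "top-layer musp")
  rng_warn(musp_b, 0.5, 1.3, "bottom-layer musp")

  media <- lapply(seq_along(wavelengths), function(i) {
    layered_medium(
      list(optical_layer(mua_t[i], musp_t[i], g = spec$g, n = spec$n),
           optical_layer(mua_b[i], musp_b[i], g = spec$g, n = spec$n)),
      thicknesses = c(spec$thickness_mm, Inf),
      n_ambient = spec$n_ambient
    )
  })
  truth <- dplyr::bind_rows(
    tibble::tibble(wavelength_nm = wavelengths, layer = "top",
                   mua = mua_t, musp = musp_t),
    tibble::tibble(wavelength_nm = wavelengths, layer = "bottom",
                   mua = mua_b, musp = musp_b)
  )
  structure(media, wavelengths = as.numeric(wavelengths), truth = truth,
            basis = basis)
}

#' Measurement noise model
#'
#' Gaussian noise applied to reflectance as
#' `rd * (1 + eps_mult) + eps_add`, clipped to `[0, 1]`, with
#' `eps_mult ~ N(0, multiplicative_sigma)` and
#' `eps_add ~ N(0, additive_sigma)`, reproducible from `seed`.
#'
#' @param multiplicative_sigma Relative standard deviation (default 0.005).
#' @param additive_sigma Absolute standard deviation (default 1e-4).
#' @param seed Integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sigma = 0.005, additive_sigma = 1e-4,
                        seed = 1L) {
  if (multiplicative_sigma < 0 || additive_sigma < 0) {
    abort("noise sigmas must be >= 0", class = "sfdlayers_input_error")
  }
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# Apply the noise contract to a vector of reflectance values (exposed for
# direct testing of the noise distribution).
apply_noise <- function(rd, noise) {
  if (noise$multiplicative_sigma == 0 && noise$additive_sigma == 0) return(rd)
  withr::with_seed(noise$seed, {
    em <- stats::rnorm(length(rd), 0, noise$multiplicative_sigma)
    ea <- stats::rnorm(length(rd), 0, noise$additive_sigma)
    pmin(1, pmax(0, rd * (1 + em) + ea))
  })
}

#' Simulate a calibrated SFDS measurement
#'
#' Runs the forward solver over the wavelength and frequency grids and
#' optionally corrupts the map with measurement noise. With
#' `demodulate = TRUE` the reflectance is additionally passed through a
#' three-phase pattern emulation (synthetic intensity triplets whose
#' modulation depth is set by Rd, demodulated back by
#' [demodulate_three_phase()]); this reproduces the direct path to numerical
#' round-off and exists to exercise the demodulation contract end to end.
#'
#' @param media Per-wavelength media from [build_media()] (or a list of
#'   [layered_medium()] plus `wavelengths`).
#' @param frequencies Spatial frequency grid, mm^-1.
#' @param noise A [noise_model()], or `NULL` for a noiseless map.
#' @param wavelengths Optional wavelength grid override.
#' @param config A [shef_config()].
#' @param demodulate Route the map through three-phase emulation.
#' @param phase0 Carrier phase offset used by the emulation.
#' @return A `reflectance_map` tibble.
#' @export
simulate_measurement <- function(media, frequencies = seq(0, 0.5, by = 0.01),
                                 noise = noise_model(), wavelengths = NULL,
                                 config = shef_config(), demodulate = FALSE,
                                 phase0 = 0) {
  map <- reflectance_map(media, frequencies, wavelengths, config)
  rd <- map$rd
  if (demodulate) {
    phases <- c(0, 2 * pi / 3, 4 * pi / 3)
    i1 <- 1 + rd * cos(phase0 + phases[1])
    i2 <- 1 + rd * cos(phase0 + phases[2])
    i3 <- 1 + rd * cos(phase0 + phases[3])
    rd <- demodulate_three_phase(i1, i2, i3)
  }
  if (!is.null(noise)) rd <- apply_noise(rd, noise)
  out <- map
  out$rd <- rd
  validate_reflectance_map(out)
}

#' Simulate a phantom measurement with ground truth
#'
#' Convenience wrapper: [build_media()] then [simulate_measurement()].
#'
#' @inheritParams simulate_measurement
#' @param spec A [phantom_spec()].
#' @param wavelengths Wavelength grid, nm.
#' @return List with elements `measurement` (reflectance map), `truth`
#'   (tibble) and `basis` (`chromophore_basis`).
#' @export
simulate_phantom <- function(spec = phantom_spec(),
                             wavelengths = analysis_wavelengths(),
                             frequencies = seq(0, 0.5, by = 0.01),
                             noise = noise_model(), config = shef_config()) {
  media <- build_media(spec, wavelengths)
  list(
    measurement = simulate_measurement(media, frequencies, noise,
                                       config = config),
    truth = attr(media, "truth"),
    basis = attr(media, "basis")
  )
}

#' Three-phase demodulation
#'
#' Recovers the AC modulation amplitude from intensities sampled at phase
#' shifts 0, 2*pi/3 and 4*pi/3:
#' `(sqrt(2)/3) * sqrt((i1-i2)^2 + (i2-i3)^2 + (i3-i1)^2)`.
#' The result is invariant to a common DC offset and to the carrier phase:
#' for `i_k = DC + a * cos(phi0 + phase_k)` it returns `a` for any `phi0`.
#'
#' @param i1,i2,i3 Intensities at the three phases (vectors allowed).
#' @return AC amplitude(s).
#' @examples
#' demodulate_three_phase(1.3, 0.85, 0.85)  # 1 + 0.3*cos(phase_k)
#' @export
demodulate_three_phase <- function(i1, i2, i3) {
  if (!all(is.finite(i1), is.finite(i2), is.finite(i3))) {
    abort("intensities must be finite", class = "sfdlayers_input_error")
  }
  sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
}
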