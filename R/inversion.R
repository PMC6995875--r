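#' Stage configuration for the four-stage inversion
#'
#' Frequency bands and optimizer settings of the staged recovery:
#' `band1` (low frequencies, representative of the bottom layer) and `band2`
#' (high frequencies, representative of the thin top layer) drive the
#' homogeneous scattering fits of stage 1; `absorption_freqs` are the two
#' lowest nonzero frequencies used for the absorption fits of stages 2 and 4;
#' `refine_freqs` combine the bottom-scattering sensitivity peak (0.06 mm^-1)
#' with a frequency that retains bottom-scattering sensitivity while
#' suppressing absorption sensitivity (0.15 mm^-1), used in stage 3.
#'
#' @param band1,band2 Stage-1 frequency bands, mm^-1.
#' @param absorption_freqs Stage-2/4 frequencies, mm^-1.
#' @param refine_freqs Stage-3 frequencies, mm^-1.
#' @param n_wavelengths Analysis wavelength count (grid 450-1000 nm).
#' @param g,n,n_ambient Forward-model assumptions used by the fits.
#' @param bounds Named list of box bounds for `mua`, `musp`, `A`, `b`, `beta`.
#' @param ftol,ptol,maxiter Levenberg-Marquardt tolerances and iteration cap.
#' @return Object of class `stage_config`.
#' @export
stage_config <- function(band1 = seq(0, 0.10, by = 0.02),
                         band2 = seq(0.30, 0.40, by = 0.02),
                         absorption_freqs = c(0.01, 0.02),
                         refine_freqs = c(0.06, 0.15),
                         n_wavelengths = 32,
                         g = 0.8, n = 1.4, n_ambient = 1,
                         bounds = list(mua = c(0, 1), musp = c(0.05, 5),
                                       A = c(0.05, 5), b = c(0, 4),
                                       beta = c(0, 10)),
                         ftol = 1e-10, ptol = 1e-8, maxiter = 60) {
  structure(list(band1 = band1, band2 = band2,
                 absorption_freqs = absorption_freqs,
                 refine_freqs = refine_freqs,
                 n_wavelengths = as.integer(n_wavelengths),
                 g = g, n = n, n_ambient = n_ambient, bounds = bounds,
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter)),
            class = "stage_config")
}

# Column indices of requested frequencies in a measurement, with a stage tag
# for actionable errors when a frequency is missing.
match_fx <- function(frequencies, wanted, stage) {
  idx <- vapply(wanted, function(f) {
    j <- which(abs(frequencies - f) < 1e-9)
    if (length(j) != 1) NA_integer_ else j
  }, 1L)
  if (anyNA(idx)) {
    abort(sprintf("%s requires spatial frequency %s mm^-1 absent from the measurement",
                  stage, paste(wanted[is.na(idx)], collapse = ", ")),
          class = "sfdlayers_input_error")
  }
  idx
}

# Nearest-neighbor subsampling of a measurement onto the analysis grid.
resample_to_grid <- function(measurement, wavelengths) {
  wl <- attr(measurement, "wavelengths")
  pick <- vapply(wavelengths, function(w) wl[which.min(abs(wl - w))], 0)
  if (anyDuplicated(pick)) {
    abort("measurement wavelength grid too coarse for the analysis grid",
          class = "sfdlayers_input_error")
  }
  out <- measurement[measurement$wavelength_nm %in% pick, ]
  validate_reflectance_map(out)
}

# Forward models used by the fits -------------------------------------------

homog_rd <- function(mua, musp, fx_vec, config, shef) {
  m <- layered_medium(list(optical_layer(mua, musp, g = config$g, n = config$n)),
                      Inf, n_ambient = config$n_ambient)
  vapply(fx_vec, function(f) solve_layered_reflectance(m, f, shef), 0)
}

two_layer_rd <- function(mua_t, musp_t, mua_b, musp_b, thickness, fx_vec,
                         config, shef) {
  m <- layered_medium(
    list(optical_layer(mua_t, musp_t, g = config$g, n = config$n),
         optical_layer(mua_b, musp_b, g = config$g, n = config$n)),
    thicknesses = c(thickness, Inf), n_ambient = config$n_ambient)
  vapply(fx_vec, function(f) solve_layered_reflectance(m, f, shef), 0)
}

#' Homogeneous power-law fit on a frequency band
#'
#' Stage-1 building block: fits a homogeneous semi-infinite medium to the
#' measured reflectance over one spatial frequency band and all wavelengths,
#' with reduced scattering constrained to the inverse power law
#' `A * (lambda/750)^-b` and absorption free per wavelength. The absorption
#' estimates are a nuisance by design (they blend both layers' absorption)
#' and are flagged discardable.
#'
#' @param measurement A `reflectance_map`.
#' @param band Spatial frequencies of the band, mm^-1 (must be present in
#'   the measurement).
#' @param config A [stage_config()]. @param shef A [shef_config()].
#' @return List with `scattering` ([power_law_scattering()]), `nuisance_mua`
#'   (tibble with `discarded = TRUE`), and `diagnostics` (residual norm,
#'   iterations, termination info).
#' @export
fit_homogeneous_band <- function(measurement, band, config = stage_config(),
                                 shef = shef_config()) {
  wl <- attr(measurement, "wavelengths")
  jb <- match_fx(attr(measurement, "frequencies"), band, "homogeneous band fit")
  obs <- rd_matrix(measurement)[, jb, drop = FALSE]
  nw <- length(wl)
  nb <- length(band)
  bd <- config$bounds

  # warm start: 2-parameter fits at a handful of wavelengths, then a
  # log-log regression for the power law
  sub <- unique(round(seq(1, nw, length.out = min(6, nw))))
  pre <- vapply(sub, function(i) {
    fit <- minpack.lm::nls.lm(
      par = c(0.05, 1),
      lower = c(bd$mua[1], bd$musp[1]), upper = c(bd$mua[2], bd$musp[2]),
      fn = function(p) homog_rd(p[1], p[2], band, config, shef) - obs[i, ],
      control = minpack.lm::nls.lm.control(maxiter = 25, ftol = 1e-8))
    fit$par
  }, c(0, 0))
  lf <- stats::lm(log(pre[2, ]) ~ log(wl[sub] / 750))
  A0 <- min(max(exp(stats::coef(lf)[1]), bd$A[1]), bd$A[2])
  b0 <- min(max(-stats::coef(lf)[2], bd$b[1]), bd$b[2])
  mua0 <- stats::approx(wl[sub], pre[1, ], xout = wl, rule = 2)$y
  mua0 <- pmin(pmax(mua0, bd$mua[1]), bd$mua[2])

  par0 <- c(A0, b0, mua0)
  lower <- c(bd$A[1], bd$b[1], rep(bd$mua[1], nw))
  upper <- c(bd$A[2], bd$b[2], rep(bd$mua[2], nw))

  model <- function(par) {
    musp <- par[1] * (wl / 750)^(-par[2])
    out <- matrix(0, nw, nb)
    for (i in seq_len(nw)) {
      out[i, ] <- homog_rd(par[2 + i], musp[i], band, config, shef)
    }
    out
  }
  fn <- function(par) as.vector(model(par) - obs)
  # structured Jacobian: A and b touch every residual, mua(lambda_i) only
  # the nb residuals of row i
  jac <- function(par) {
    base <- model(par)
    J <- matrix(0, nw * nb, length(par))
    for (k in 1:2) {
      h <- 1e-6 * max(1, abs(par[k]))
      ph <- par; ph[k] <- par[k] + h
      J[, k] <- as.vector(model(ph) - base) / h
    }
    for (i in seq_len(nw)) {
      k <- 2 + i
      h <- 1e-6 * max(0.01, abs(par[k]))
      musp_i <- par[1] * (wl[i] / 750)^(-par[2])
      J[(seq_len(nb) - 1) * nw + i, k] <-
        (homog_rd(par[k] + h, musp_i, band, config, shef) - base[i, ]) / h
    }
    J
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                         ftol = config$ftol,
                                         ptol = config$ptol))
  if (fit$info == 0 || fit$info == 9) {
    warn(sprintf("homogeneous band fit did not converge (info %d, residual %.3g)",
                 fit$info, sqrt(fit$deviance)),
         class = "sfdlayers_convergence_warning")
  }
  list(
    scattering = power_law_scattering(fit$par[1], fit$par[2]),
    nuisance_mua = tibble::tibble(wavelength_nm = wl, mua = fit$par[-(1:2)],
                                  discarded = TRUE),
    diagnostics = list(residual_norm = sqrt(fit$deviance),
                       iterations = fit$niter, info = fit$info,
                       band = band)
  )
}

#' Stage 1: layer-specific reduced scattering power laws
#'
#' Fits a homogeneous medium separately on the low band (`band1`,
#' representative of the bottom layer) and the high band (`band2`,
#' representative of the top layer). Absorption estimates from both fits are
#' discarded.
#'
#' @inheritParams fit_homogeneous_band
#' @return List with `top`, `bottom` ([power_law_scattering()]), the two
#'   nuisance absorption tibbles and diagnostics.
#' @export
stage1 <- function(measurement, config = stage_config(),
                   shef = shef_config()) {
  low <- fit_homogeneous_band(measurement, config$band1, config, shef)
  high <- fit_homogeneous_band(measurement, config$band2, config, shef)
  list(top = high$scattering, bottom = low$scattering,
       nuisance = list(band1 = low$nuisance_mua, band2 = high$nuisance_mua),
       diagnostics = list(band1 = low$diagnostics, band2 = high$diagnostics))
}

#' Stage 2: absorption spectra with a known bottom-layer shape
#'
#' Joint bounded least squares over the two lowest nonzero frequencies and
#' all wavelengths. Unknowns: the scalar `beta` multiplying the known
#' bottom-layer absorption basis, plus the top-layer absorption at each
#' wavelength (dimension `n_wavelengths + 1` for a single chromophore).
#' Both layers' reduced scattering spectra are held at their stage-1 power
#' laws.
#'
#' @param measurement A `reflectance_map`.
#' @param scattering Stage-1 output (list with `top`, `bottom`).
#' @param basis A `chromophore_basis` covering the measurement grid.
#' @param thickness Top-layer thickness, mm.
#' @param config,shef Configurations.
#' @return List with `beta`, `top_mua` (tibble), `n_unknowns`, diagnostics.
#' @export
stage2 <- function(measurement, scattering, basis, thickness,
                   config = stage_config(), shef = shef_config()) {
  wl <- attr(measurement, "wavelengths")
  jb <- match_fx(attr(measurement, "frequencies"), config$absorption_freqs,
                 "stage 2")
  obs <- rd_matrix(measurement)[, jb, drop = FALSE]
  fxs <- config$absorption_freqs
  nw <- length(wl)
  nb <- length(fxs)
  bd <- config$bounds
  musp_t <- musp_at(scattering$top, wl)
  musp_b <- musp_at(scattering$bottom, wl)
  shape <- basis_on_grid(basis, wl, "stage 2 basis")

  model <- function(par) {
    out <- matrix(0, nw, nb)
    for (i in seq_len(nw)) {
      out[i, ] <- two_layer_rd(par[1 + i], musp_t[i], par[1] * shape[i],
                               musp_b[i], thickness, fxs, config, shef)
    }
    out
  }
  fn <- function(par) as.vector(model(par) - obs)
  jac <- function(par) {
    base <- model(par)
    J <- matrix(0, nw * nb, length(par))
    h <- 1e-6 * max(1, abs(par[1]))
    ph <- par; ph[1] <- par[1] + h
    J[, 1] <- as.vector(model(ph) - base) / h
    for (i in seq_len(nw)) {
      k <- 1 + i
      h <- 1e-6 * max(0.01, abs(par[k]))
      J[(seq_len(nb) - 1) * nw + i, k] <-
        (two_layer_rd(par[k] + h, musp_t[i], par[1] * shape[i], musp_b[i],
                      thickness, fxs, config, shef) - base[i, ]) / h
    }
    J
  }
  par0 <- c(0.5, rep(0.05, nw))
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = c(bd$beta[1], rep(bd$mua[1], nw)),
    upper = c(bd$beta[2], rep(bd$mua[2], nw)),
    fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                         ftol = config$ftol,
                                         ptol = config$ptol))
  if (fit$info == 0 || fit$info == 9) {
    warn(sprintf("stage 2 did not converge (info %d)", fit$info),
         class = "sfdlayers_convergence_warning")
  }
  list(beta = fit$par[1],
       top_mua = tibble::tibble(wavelength_nm = wl, mua = fit$par[-1]),
       n_unknowns = length(par0),
       diagnostics = list(residual_norm = sqrt(fit$deviance),
                          iterations = fit$niter, info = fit$info))
}

# Shared machinery of stages 3 and 4: independent bounded 1-parameter fits
# per wavelength, with a per-wavelength fallback to the prior value.
per_wavelength_fit <- function(obs, start, lower, upper, objective, stage) {
  nw <- nrow(obs)
  est <- numeric(nw)
  fallback <- logical(nw)
  conv <- integer(nw)
  for (i in seq_len(nw)) {
    res <- tryCatch({
      fit <- stats::nlminb(start[i], function(p) objective(i, p),
                           lower = lower, upper = upper,
                           control = list(abs.tol = 1e-14, rel.tol = 1e-12))
      list(par = fit$par, conv = fit$convergence)
    }, error = function(e) NULL)
    if (is.null(res)) {
      est[i] <- start[i]
      fallback[i] <- TRUE
    } else {
      est[i] <- res$par
      conv[i] <- res$conv
    }
  }
  if (any(fallback)) {
    warn(sprintf("%s: fit failed at %d wavelength(s); prior value retained",
                 stage, sum(fallback)),
         class = "sfdlayers_fallback_warning")
  }
  list(est = est, fallback = fallback, convergence = conv)
}

#' Stage 3: per-wavelength refinement of bottom-layer scattering
#'
#' Drops the power-law constraint on the bottom layer and refits its reduced
#' scattering at each wavelength independently (1-parameter bounded least
#' squares on the stage-3 frequencies), holding the top scattering (stage 1)
#' and both absorption spectra (stage 2) fixed. Initial guess per wavelength:
#' the stage-1 bottom power law. Failed wavelengths fall back to that value
#' and are flagged.
#'
#' @param measurement A `reflectance_map`.
#' @param prior List with stage-1 `scattering` and stage-2 `beta`/`top_mua`.
#' @param basis The bottom-layer absorption basis.
#' @param thickness Top-layer thickness, mm.
#' @param config,shef Configurations.
#' @return Tibble `wavelength_nm`, `musp`, `fallback`.
#' @export
stage3 <- function(measurement, prior, basis, thickness,
                   config = stage_config(), shef = shef_config()) {
  wl <- attr(measurement, "wavelengths")
  jb <- match_fx(attr(measurement, "frequencies"), config$refine_freqs,
                 "stage 3")
  obs <- rd_matrix(measurement)[, jb, drop = FALSE]
  fxs <- config$refine_freqs
  musp_t <- musp_at(prior$scattering$top, wl)
  mua_t <- prior$top_mua$mua
  mua_b <- prior$beta * basis_on_grid(basis, wl, "stage 3 basis")
  start <- musp_at(prior$scattering$bottom, wl)
  bd <- config$bounds
  obj <- function(i, p) {
    sum((two_layer_rd(mua_t[i], musp_t[i], mua_b[i], p, thickness, fxs,
                      config, shef) - obs[i, ])^2)
  }
  r <- per_wavelength_fit(obs, start, bd$musp[1], bd$musp[2], obj, "stage 3")
  tibble::tibble(wavelength_nm = wl, musp = r$est, fallback = r$fallback)
}

#' Stage 4: per-wavelength refinement of top-layer absorption
#'
#' Refits the top-layer absorption at each wavelength on the low-frequency
#' pair, fixing top scattering (stage 1), bottom absorption (stage 2) and
#' bottom scattering (stage 3). Initial guess: the stage-2 top absorption.
#' Estimates driven to the zero bound are flagged (`at_floor`): with very
#' low superficial absorption the measurement carries little information and
#' underestimation toward zero is expected behavior.
#'
#' @param measurement A `reflectance_map`.
#' @param prior List with stage-1 `scattering`, stage-2 `beta`/`top_mua`,
#'   stage-3 `bottom_musp` tibble.
#' @param basis The bottom-layer absorption basis.
#' @param thickness Top-layer thickness, mm.
#' @param config,shef Configurations.
#' @return Tibble `wavelength_nm`, `mua`, `fallback`, `at_floor`.
#' @export
stage4 <- function(measurement, prior, basis, thickness,
                   config = stage_config(), shef = shef_config()) {
  wl <- attr(measurement, "wavelengths")
  jb <- match_fx(attr(measurement, "frequencies"), config$absorption_freqs,
                 "stage 4")
  obs <- rd_matrix(measurement)[, jb, drop = FALSE]
  fxs <- config$absorption_freqs
  musp_t <- musp_at(prior$scattering$top, wl)
  musp_b <- prior$bottom_musp$musp
  mua_b <- prior$beta * basis_on_grid(basis, wl, "stage 4 basis")
  start <- pmax(prior$top_mua$mua, 1e-4)
  bd <- config$bounds
  obj <- function(i, p) {
    sum((two_layer_rd(p, musp_t[i], mua_b[i], musp_b[i], thickness, fxs,
                      config, shef) - obs[i, ])^2)
  }
  r <- per_wavelength_fit(obs, start, bd$mua[1], bd$mua[2], obj, "stage 4")
  tibble::tibble(wavelength_nm = wl, mua = r$est, fallback = r$fallback,
                 at_floor = r$est <= bd$mua[1] + 1e-5)
}

#' Four-stage recovery of layered optical property spectra
#'
#' Runs the full staged inversion on a multispectral SFDS measurement with
#' known top-layer thickness and known bottom-layer absorption shape:
#' stage 1 recovers per-layer reduced scattering power laws from two
#' frequency bands, stage 2 recovers `beta` (bottom absorption) and a
#' provisional top absorption spectrum at low frequencies, stage 3 refines
#' the bottom scattering per wavelength, and stage 4 refines the top
#' absorption per wavelength. The procedure is deterministic: initial
#' guesses are fixed and documented, and no randomization is used.
#'
#' @param measurement A `reflectance_map` covering all configured
#'   frequencies; wavelength grids larger than `config$n_wavelengths` are
#'   subsampled to the analysis grid by nearest neighbor.
#' @param basis A `chromophore_basis` covering the analysis grid.
#' @param thickness Top-layer thickness, mm (known a priori).
#' @param config A [stage_config()]. @param shef A [shef_config()].
#' @return Object of class `sfd_inversion`: per-stage snapshots, the final
#'   four spectra, `beta`, and fit diagnostics.
#' @export
run_staged_inversion <- function(measurement, basis, thickness,
                                 config = stage_config(),
                                 shef = shef_config()) {
  stopifnot(inherits(measurement, "reflectance_map"))
  freqs <- attr(measurement, "frequencies")
  match_fx(freqs, config$band1, "stage 1 (band 1)")
  match_fx(freqs, config$band2, "stage 1 (band 2)")
  match_fx(freqs, config$absorption_freqs, "stage 2/4")
  match_fx(freqs, config$refine_freqs, "stage 3")
  if (length(attr(measurement, "wavelengths")) > config$n_wavelengths) {
    measurement <- resample_to_grid(measurement,
                                    analysis_wavelengths(config$n_wavelengths))
  }
  wl <- attr(measurement, "wavelengths")

  s1 <- stage1(measurement, config, shef)
  s2 <- stage2(measurement, s1, basis, thickness, config, shef)
  s3 <- stage3(measurement,
               list(scattering = s1, beta = s2$beta, top_mua = s2$top_mua),
               basis, thickness, config, shef)
  s4 <- stage4(measurement,
               list(scattering = s1, beta = s2$beta, top_mua = s2$top_mua,
                    bottom_musp = s3),
               basis, thickness, config, shef)

  shape <- basis_on_grid(basis, wl, "basis")
  spectra <- dplyr::bind_rows(
    tibble::tibble(wavelength_nm = wl, layer = "top", property = "musp",
                   value = musp_at(s1$top, wl), stage = 1L),
    tibble::tibble(wavelength_nm = wl, layer = "bottom", property = "musp",
                   value = musp_at(s1$bottom, wl), stage = 1L),
    tibble::tibble(wavelength_nm = wl, layer = "bottom", property = "mua",
                   value = s2$beta * shape, stage = 2L),
    tibble::tibble(wavelength_nm = wl, layer = "top", property = "mua",
                   value = s2$top_mua$mua, stage = 2L),
    tibble::tibble(wavelength_nm = wl, layer = "bottom", property = "musp",
                   value = s3$musp, stage = 3L),
    tibble::tibble(wavelength_nm = wl, layer = "top", property = "mua",
                   value = s4$mua, stage = 4L)
  )
  if (any(spectra$value < 0)) {
    abort("internal error: negative recovered spectrum",
          class = "sfdlayers_internal_error")
  }
  structure(list(
    top_scattering = s1$top,
    bottom_scattering = s3[, c("wavelength_nm", "musp")],
    beta = s2$beta,
    top_absorption = s4[, c("wavelength_nm", "mua")],
    stages = list(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4),
    spectra = spectra,
    wavelengths = wl, thickness = thickness,
    config = config, shef = shef
  ), class = "sfd_inversion")
}

#' @export
print.sfd_inversion <- function(x, ...) {
  cat("<sfd_inversion>\n")
  cat(sprintf("  wavelengths: %d (%g-%g nm), top thickness %g mm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$thickness))
  cat(sprintf("  stage 1: top musp' = %.3g*(lambda/750)^-%.3g, bottom A=%.3g b=%.3g\n",
              x$top_scattering$A, x$top_scattering$b,
              x$stages$stage1$bottom$A, x$stages$stage1$bottom$b))
  cat(sprintf("  stage 2: beta = %.4g (%d unknowns)\n", x$beta,
              x$stages$stage2$n_unknowns))
  cat(sprintf("  stage 3: bottom musp' refined per wavelength (%d fallback)\n",
              sum(x$stages$stage3$fallback)))
  cat(sprintf("  stage 4: top mua refined per wavelength (%d at floor)\n",
              sum(x$stages$stage4$at_floor)))
  invisible(x)
}

#' Tidy the recovered spectra of a staged inversion
#'
#' @param x An `sfd_inversion`.
#' @param stages Which stage snapshots to include (default: all).
#' @param ... Unused.
#' @return Tibble with columns `wavelength_nm`, `layer`, `property`,
#'   `value`, `stage`.
#' @export
tidy.sfd_inversion <- function(x, stages = 1:4, ...) {
  dplyr::filter(x$spectra, .data$stage %in% stages)
}

#' One-row summary of a staged inversion
#'
#' @param x An `sfd_inversion`. @param ... Unused.
#' @return One-row tibble: `beta`, per-stage residual norms and iteration
#'   counts, fallback/floor counts.
#' @export
glance.sfd_inversion <- function(x, ...) {
  d1 <- x$stages$stage1$diagnostics
  d2 <- x$stages$stage2$diagnostics
  tibble::tibble(
    beta = x$beta,
    stage1_rss_band1 = d1$band1$residual_norm,
    stage1_rss_band2 = d1$band2$residual_norm,
    stage1_iter = d1$band1$iterations + d1$band2$iterations,
    stage2_rss = d2$residual_norm,
    stage2_iter = d2$iterations,
    stage2_unknowns = x$stages$stage2$n_unknowns,
    stage3_fallbacks = sum(x$stages$stage3$fallback),
    stage4_at_floor = sum(x$stages$stage4$at_floor)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
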