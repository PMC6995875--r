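# Per-layer eigenmode cache. Keys encode every input that determines the
# decomposition, so memoization is exact; the cache is wiped when it grows
# past a few hundred entries to bound memory during long fits.
.mode_cache <- new.env(parent = emptyenv())

layer_modes <- function(mua, musp, g, n, fx, order, mode_floor) {
  key <- sprintf("%.17g|%.17g|%.17g|%.17g|%.17g|%d|%.6g",
                 mua, musp, g, n, fx, order, mode_floor)
  hit <- .mode_cache[[key]]
  if (!is.null(hit)) return(hit)

  ops <- sh_operators(order)
  # degenerate case fx = 0, mua = 0: a zero transport eigenvalue appears;
  # perturb the absorption by mode_floor (documented contract).
  if (fx == 0 && mua < mode_floor) mua <- mua + mode_floor
  mus <- musp / (1 - g)
  # delta-M scaling: fold the truncated forward peak of the phase function
  # into unscattered transport. Essential for order-N convergence with a
  # collimated source and forward-peaked scattering; leaves musp invariant.
  moms <- phase_moments(g, order + 1)
  f_dm <- moms[order + 2]
  mus <- mus * (1 - f_dm)
  gl <- (moms[1:(order + 1)] - f_dm) / (1 - f_dm)
  mut <- mua + mus
  sigma <- mua + mus * (1 - gl[ops$idx$l + 1])
  k <- 2 * pi * fx
  B <- diag(sigma)
  if (k > 0) B <- B + k * ops$Ax_signed
  G <- solve(B, ops$Az)
  e <- eigen(G)
  nu <- e$values

  ord <- order(Mod(nu))
  drop_idx <- ord[seq_len(ops$n_null)]
  keep <- sort(setdiff(seq_along(nu), drop_idx))
  if (ops$n_null > 0) {
    max_drop <- max(Mod(nu[drop_idx]))
    min_keep <- min(Mod(nu[keep]))
    if (!(max_drop < 1e-6 * min_keep)) {
      abort(sprintf(paste0("eigenmode degeneracy: null/finite eigenvalue gap ",
                           "collapsed (%.3g vs %.3g) at fx=%g"),
                    max_drop, min_keep, fx),
            class = "sfdlayers_conditioning_error")
    }
  }
  kappa <- -1 / nu[keep]
  W <- e$vectors[, keep, drop = FALSE]
  if (is.complex(kappa) && max(abs(Im(kappa))) == 0) {
    kappa <- Re(kappa); W <- Re(W)
  }
  dec <- Re(kappa) < 0
  if (sum(dec) != length(kappa) / 2) {
    abort(sprintf("decaying/growing eigenmode split is %d/%d at fx=%g",
                  sum(dec), sum(!dec), fx),
          class = "sfdlayers_conditioning_error")
  }

  # particular solution for the first-scatter source q0 * exp(-mut * depth)
  q0 <- mus * gl[ops$idx$l + 1] * ops$Yz
  Ap <- B - mut * ops$Az
  u <- tryCatch(solve(Ap, q0), error = function(e) {
    solve(B - (mut * (1 + 1e-9) + 1e-12) * ops$Az, q0)
  })

  val <- list(kappa = kappa, W = W, dec = dec, mut = mut, u = u)
  if (length(ls(.mode_cache)) > 400) {
    rm(list = ls(.mode_cache), envir = .mode_cache)
  }
  assign(key, val, envir = .mode_cache)
  val
}

#' Depth-evolution operator of one layer
#'
#' Assembles the order-N spherical-harmonic depth operator of a single layer
#' at one spatial frequency. The radiance coefficient vector c(z) (length
#' `(order + 1)^2`) evolves as `streaming %*% dc/dz = -collision %*% c` plus
#' source terms; `streaming` is the direction-cosine coupling matrix and
#' `collision` combines attenuation (`mua + mus * (1 - g^l)` on the diagonal)
#' with the transverse-frequency coupling, whose entries scale with
#' `2 * pi * fx`. At `fx = 0` the collision matrix is diagonal, so the system
#' block-decouples across azimuthal orders m and the m = 0 block is the
#' classical azimuthally symmetric P_N assembly.
#'
#' The transverse coupling is stored in a similarity-transformed real form
#' (coefficients of odd azimuthal order are rescaled by the imaginary unit),
#' which is how the solver consumes it.
#'
#' @param layer An [optical_layer()].
#' @param fx Spatial frequency, mm^-1 (>= 0).
#' @param config A [shef_config()].
#' @return A list of class `shef_operator` with elements `streaming`,
#'   `collision`, `index` (the basis table) and `dim`.
#' @export
assemble_layer_operator <- function(layer, fx, config = shef_config()) {
  stopifnot(inherits(layer, "optical_layer"), fx >= 0)
  ops <- sh_operators(config$order)
  mua <- layer$mua
  if (fx == 0 && mua < config$mode_floor) mua <- mua + config$mode_floor
  mus <- layer$musp / (1 - layer$g)
  gl <- phase_moments(layer$g, config$order)
  sigma <- mua + mus * (1 - gl[ops$idx$l + 1])
  B <- diag(sigma)
  if (fx > 0) B <- B + 2 * pi * fx * ops$Ax_signed
  structure(list(streaming = ops$Az, collision = B, index = ops$idx,
                 dim = ops$K),
            class = "shef_operator")
}

#' Spatial frequency-domain diffuse reflectance of a layered medium
#'
#' Solves the order-N spherical-harmonic transport system for a stack of
#' layers under normally incident, sinusoidally modulated collimated
#' illumination of unit AC amplitude, and returns the calibrated diffuse
#' reflectance (the AC reflectance transfer function, specular excluded).
#'
#' Each layer is eigendecomposed into exponential depth modes; only decaying
#' modes are retained in the semi-infinite bottom layer, finite layers keep
#' both families with exponentials referenced to the nearest interface to
#' avoid overflow. Mode amplitudes are fixed by Marshak half-range conditions
#' with Fresnel internal reflection at the top surface and by continuity of
#' the streaming flux moments at each interior (index-matched) interface.
#' The collimated beam enters as a Beer-Lambert attenuated first-scatter
#' source.
#'
#' @param medium A [layered_medium()].
#' @param fx Scalar spatial frequency, mm^-1.
#' @param config A [shef_config()].
#' @return Diffuse reflectance Rd in \[0, 1\].
#' @examples
#' m <- layered_medium(list(optical_layer(0.01, 1.0)), Inf)
#' solve_layered_reflectance(m, fx = 0.1)
#' @export
solve_layered_reflectance <- function(medium, fx, config = shef_config()) {
  stopifnot(inherits(medium, "layered_medium"))
  if (!is.numeric(fx) || length(fx) != 1 || !is.finite(fx) || fx < 0) {
    abort("fx must be a finite scalar >= 0", class = "sfdlayers_input_error")
  }
  ops <- sh_operators(config$order)
  K <- ops$K
  L <- length(medium$layers)
  n_med <- medium$layers[[1]]$n
  M <- marshak_matrix(config$order, n_med, medium$n_ambient)
  tw <- exit_weights(config$order, n_med, medium$n_ambient)
  Tin <- 1 - fresnel_reflectance(1, medium$n_ambient, n_med)

  modes <- lapply(medium$layers, function(ly) {
    layer_modes(ly$mua, ly$musp, ly$g, ly$n, fx, config$order, config$mode_floor)
  })
  d <- medium$thicknesses
  atten <- numeric(L)
  atten[1] <- Tin
  if (L > 1) for (j in 2:L) atten[j] <- atten[j - 1] * exp(-modes[[j - 1]]$mut * d[j - 1])

  cols <- lapply(seq_len(L), function(j) {
    if (j < L) seq_along(modes[[j]]$kappa) else which(modes[[j]]$dec)
  })
  ncol_j <- vapply(cols, length, 0L)
  offs <- cumsum(c(0L, ncol_j))
  ntot <- offs[L + 1]
  cplx <- any(vapply(modes, function(m) is.complex(m$kappa), TRUE))
  zero <- if (cplx) 0 + 0i else 0
  A <- matrix(zero, ntot, ntot)
  rhs <- rep(zero, ntot)

  # basis of layer j evaluated at local depth zeta in [0, d_j]:
  # decaying modes referenced to the layer top, growing to the layer bottom
  phi_at <- function(j, zeta) {
    mj <- modes[[j]]
    kap <- mj$kappa[cols[[j]]]
    ref <- ifelse(Re(kap) < 0, 0, d[j])
    sc <- exp(kap * (zeta - ref))
    mj$W[, cols[[j]], drop = FALSE] * rep(sc, each = K)
  }

  nm <- nrow(M)
  rows_top <- seq_len(nm)
  A[rows_top, offs[1] + seq_len(ncol_j[1])] <- M %*% phi_at(1, 0)
  rhs[rows_top] <- -(M %*% (modes[[1]]$u * atten[1]))
  if (L > 1) {
    nu_rows <- nrow(ops$Ut)
    for (j in seq_len(L - 1)) {
      r <- nm + (j - 1) * nu_rows + seq_len(nu_rows)
      A[r, offs[j] + seq_len(ncol_j[j])] <- ops$Ut %*% phi_at(j, d[j])
      A[r, offs[j + 1] + seq_len(ncol_j[j + 1])] <- -(ops$Ut %*% phi_at(j + 1, 0))
      pj  <- modes[[j]]$u * atten[j] * exp(-modes[[j]]$mut * d[j])
      pj1 <- modes[[j + 1]]$u * atten[j + 1]
      rhs[r] <- -(ops$Ut %*% (pj - pj1))
    }
  }

  a <- tryCatch(solve(A, rhs), error = function(e) {
    abort(sprintf("layered mode system is singular at fx=%g: %s",
                  fx, conditionMessage(e)),
          class = "sfdlayers_conditioning_error")
  })
  c0 <- phi_at(1, 0) %*% a[offs[1] + seq_len(ncol_j[1])] +
    modes[[1]]$u * atten[1]
  rd <- sum(tw * c0)
  if (is.complex(rd)) {
    if (abs(Im(rd)) > 1e-7 && abs(Im(rd)) > 1e-4 * abs(Re(rd))) {
      abort(sprintf("non-real reflectance (Im = %.3g) at fx=%g", Im(rd), fx),
            class = "sfdlayers_conditioning_error")
    }
    rd <- Re(rd)
  }
  if (!is.finite(rd) || rd < -1e-6 || rd > 1 + 1e-6) {
    abort(sprintf("reflectance %.6g outside [0, 1] at fx=%g", rd, fx),
          class = "sfdlayers_conditioning_error")
  }
  min(1, max(0, rd))
}

new_reflectance_map <- function(wavelengths, frequencies, rd) {
  rd <- as.matrix(rd)
  stopifnot(nrow(rd) == length(wavelengths), ncol(rd) == length(frequencies))
  out <- tidyr::expand_grid(wavelength_nm = as.numeric(wavelengths),
                            fx_per_mm = as.numeric(frequencies))
  out$rd <- as.vector(t(rd))
  validate_reflectance_map(out)
}

validate_reflectance_map <- function(tbl) {
  need <- c("wavelength_nm", "fx_per_mm", "rd")
  if (!all(need %in% names(tbl))) {
    abort("a reflectance map needs columns wavelength_nm, fx_per_mm, rd",
          class = "sfdlayers_input_error")
  }
  bad <- which(!is.finite(tbl$rd) | tbl$rd < 0 | tbl$rd > 1)
  if (length(bad)) {
    abort(sprintf("rd outside [0, 1] at %d cell(s), first at wavelength %g nm, fx %g mm^-1",
                  length(bad), tbl$wavelength_nm[bad[1]], tbl$fx_per_mm[bad[1]]),
          class = "sfdlayers_validation_error")
  }
  wl <- sort(unique(tbl$wavelength_nm))
  fx <- sort(unique(tbl$fx_per_mm))
  if (nrow(tbl) != length(wl) * length(fx)) {
    abort("reflectance map grid is incomplete (not a full wavelength x fx crossing)",
          class = "sfdlayers_validation_error")
  }
  tbl <- dplyr::arrange(tibble::as_tibble(tbl), .data$wavelength_nm, .data$fx_per_mm)
  structure(tbl, wavelengths = wl, frequencies = fx,
            class = c("reflectance_map", class(tibble::tibble())))
}

#' Reflectance matrix of a map
#'
#' @param map A `reflectance_map` tibble.
#' @return Numeric matrix, wavelengths in rows (ascending), frequencies in
#'   columns (ascending), dimnames set accordingly.
#' @export
rd_matrix <- function(map) {
  wl <- attr(map, "wavelengths") %||% sort(unique(map$wavelength_nm))
  fx <- attr(map, "frequencies") %||% sort(unique(map$fx_per_mm))
  m <- matrix(NA_real_, length(wl), length(fx),
              dimnames = list(format(wl), format(fx)))
  i <- match(map$wavelength_nm, wl)
  j <- match(map$fx_per_mm, fx)
  m[cbind(i, j)] <- map$rd
  m
}

#' Forward reflectance map over a wavelength and frequency grid
#'
#' Runs [solve_layered_reflectance()] for one medium per wavelength over a
#' common spatial frequency grid. Entries are mutually independent, so the
#' result does not depend on evaluation order.
#'
#' @param media List of [layered_medium()] objects, one per wavelength.
#' @param frequencies Spatial frequency grid, mm^-1.
#' @param wavelengths Wavelength grid, nm (defaults to the `wavelengths`
#'   attribute of `media` when present).
#' @param config A [shef_config()].
#' @return A `reflectance_map` tibble with columns `wavelength_nm`,
#'   `fx_per_mm`, `rd`.
#' @export
reflectance_map <- function(media, frequencies, wavelengths = NULL,
                            config = shef_config()) {
  if (inherits(media, "layered_medium")) media <- list(media)
  wavelengths <- wavelengths %||% attr(media, "wavelengths")
  if (is.null(wavelengths)) {
    abort("supply `wavelengths` (or media built by build_media())",
          class = "sfdlayers_input_error")
  }
  if (length(media) != length(wavelengths)) {
    abort("need exactly one medium per wavelength",
          class = "sfdlayers_input_error")
  }
  rd <- matrix(NA_real_, length(wavelengths), length(frequencies))
  for (i in seq_along(media)) {
    for (j in seq_along(frequencies)) {
      rd[i, j] <- tryCatch(
        solve_layered_reflectance(media[[i]], frequencies[j], config),
        error = function(e) {
          abort(sprintf("forward solve failed at wavelength %g nm, fx %g mm^-1: %s",
                        wavelengths[i], frequencies[j], conditionMessage(e)),
                class = "sfdlayers_solver_error")
        })
    }
  }
  new_reflectance_map(wavelengths, frequencies, rd)
}
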