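# Unit tests run at reduced wavelength counts; the full 32-wavelength
# phantom recovery lives in test-acceptance.R.

wl6 <- analysis_wavelengths(6)
cfg6 <- stage_config(n_wavelengths = 6)

test_that("homogeneous band fit recovers a power-law medium exactly (inverse crime)", {
  pl <- power_law_scattering(1.0, 1.2)
  mua <- 0.02 + 0.05 * exp(-(wl6 - 550)^2 / (2 * 60^2))  # smooth spectrum
  media <- lapply(seq_along(wl6), function(i) {
    layered_medium(list(optical_layer(mua[i], musp_at(pl, wl6[i]))), Inf)
  })
  band <- cfg6$band1
  meas <- reflectance_map(media, band, wavelengths = wl6)
  fit <- fit_homogeneous_band(meas, band, cfg6)
  expect_lt(abs(fit$scattering$A - 1.0), 0.01)
  expect_lt(abs(fit$scattering$b - 1.2), 0.01 * 1.2)
  # measurement equals the model at the optimum: residual norm ~ 0
  expect_lt(fit$diagnostics$residual_norm, 1e-6)
  expect_true(all(fit$nuisance_mua$discarded))
  expect_rel_equal(fit$nuisance_mua$mua, mua, 0.02)
  expect_error(fit_homogeneous_band(meas, c(0.25), cfg6),
               class = "sfdlayers_input_error")
})

test_that("high band tracks the top layer, low band the bottom layer", {
  # phantom-like contrast: a strongly scattering thin top over a weaker base
  spec <- phantom_spec(
    top_scattering = power_law_scattering(1.3, 1.5),
    bottom_scattering = power_law_scattering(0.8, 1.0))
  sim <- suppressWarnings(
    simulate_phantom(spec, wl6, inversion_frequencies(), noise = NULL,
                     config = shef_config()))
  s1 <- stage1(sim$measurement, cfg6)
  top_truth <- musp_at(spec$top_scattering, wl6)
  bot_truth <- musp_at(spec$bottom_scattering, wl6)
  rel_l2 <- function(x, y) sqrt(sum((x - y)^2)) / sqrt(sum(y^2))
  est_top <- musp_at(s1$top, wl6)
  est_bot <- musp_at(s1$bottom, wl6)
  expect_lt(rel_l2(est_top, top_truth), rel_l2(est_top, bot_truth))
  expect_lt(rel_l2(est_bot, bot_truth), rel_l2(est_bot, top_truth))

  # swapping the bands swaps the layer assignments
  cfg_sw <- cfg6
  cfg_sw$band1 <- cfg6$band2
  cfg_sw$band2 <- cfg6$band1
  s1_sw <- stage1(sim$measurement, cfg_sw)
  expect_equal(s1_sw$top$A, s1$bottom$A)
  expect_equal(s1_sw$bottom$b, s1$top$b)
})

test_that("identical layers yield matching top and bottom power laws", {
  pl <- power_law_scattering(1.0, 1.1)
  mua <- rep(0.05, length(wl6))
  media <- lapply(seq_along(wl6), function(i) {
    ly <- optical_layer(mua[i], musp_at(pl, wl6[i]))
    layered_medium(list(ly, ly), c(0.3, Inf))
  })
  meas <- reflectance_map(media, inversion_frequencies(), wavelengths = wl6)
  s1 <- stage1(meas, cfg6)
  expect_rel_equal(musp_at(s1$top, wl6), musp_at(s1$bottom, wl6), 0.02)
})

make_two_layer_sim <- function(mua_t_vec, beta = 1, wl = wl6) {
  basis <- hemoglobin_like_basis(wl)
  pl_t <- power_law_scattering(1.1, 1.3)
  pl_b <- power_law_scattering(1.0, 1.2)
  media <- lapply(seq_along(wl), function(i) {
    layered_medium(
      list(optical_layer(mua_t_vec[i], musp_at(pl_t, wl[i])),
           optical_layer(beta * basis$mua_per_unit[i], musp_at(pl_b, wl[i]))),
      c(0.3, Inf))
  })
  list(meas = reflectance_map(media, c(0.01, 0.02, 0.06, 0.15),
                              wavelengths = wl),
       basis = basis, pl_t = pl_t, pl_b = pl_b)
}

test_that("stage 2 dimensionality, beta recovery and the zero-absorption top layer", {
  sim <- make_two_layer_sim(rep(0, length(wl6)), beta = 1)
  s2 <- stage2(sim$meas, list(top = sim$pl_t, bottom = sim$pl_b),
               sim$basis, 0.3, cfg6)
  # unknown vector: one beta plus one top mua per wavelength
  expect_equal(s2$n_unknowns, length(wl6) + 1)
  expect_gte(s2$beta, 0.9)
  expect_lte(s2$beta, 1.1)
  expect_true(all(s2$top_mua$mua <= 1e-3))
})

test_that("stage 3 refines only where the truth departs from the power law", {
  # truth follows the power law exactly: stage 3 stays within 1% of stage 1
  sim <- make_two_layer_sim(rep(0.02, length(wl6)))
  prior <- list(scattering = list(top = sim$pl_t, bottom = sim$pl_b),
                beta = 1, top_mua = tibble::tibble(wavelength_nm = wl6,
                                                   mua = rep(0.02, 6)))
  s3 <- stage3(sim$meas, prior, sim$basis, 0.3, cfg6)
  expect_rel_equal(s3$musp, musp_at(sim$pl_b, wl6), 0.01)
  expect_false(any(s3$fallback))
})

test_that("stage 3 recovers ripple structure a power law cannot represent", {
  wl8 <- analysis_wavelengths(8)
  basis <- hemoglobin_like_basis(wl8)
  pl_t <- power_law_scattering(1.1, 1.3)
  pl_b <- power_law_scattering(1.0, 1.2)
  ripple <- musp_at(pl_b, wl8) * (1 + 0.05 * sin(2 * pi * (wl8 - 450) / 180))
  media <- lapply(seq_along(wl8), function(i) {
    layered_medium(
      list(optical_layer(0.02, musp_at(pl_t, wl8[i])),
           optical_layer(basis$mua_per_unit[i], ripple[i])),
      c(0.3, Inf))
  })
  meas <- reflectance_map(media, c(0.01, 0.02, 0.06, 0.15), wavelengths = wl8)
  # stage-1-like prior: the best power-law representation of the rippled truth
  lf <- stats::lm(log(ripple) ~ log(wl8 / 750))
  pl_fit <- power_law_scattering(exp(coef(lf)[1]), -coef(lf)[2])
  prior <- list(scattering = list(top = pl_t, bottom = pl_fit), beta = 1,
                top_mua = tibble::tibble(wavelength_nm = wl8,
                                         mua = rep(0.02, 8)))
  s3 <- stage3(meas, prior, basis, 0.3, stage_config(n_wavelengths = 8))
  err1 <- abs(musp_at(pl_fit, wl8) - ripple) / ripple
  err3 <- abs(s3$musp - ripple) / ripple
  expect_gte(mean(err3 <= err1 + 1e-12), 0.75)
  expect_lt(stats::median(err3), stats::median(err1))
})

test_that("stage 3 results are independent across wavelengths", {
  sim <- make_two_layer_sim(rep(0.02, length(wl6)))
  prior <- list(scattering = list(top = sim$pl_t, bottom = sim$pl_b),
                beta = 1, top_mua = tibble::tibble(wavelength_nm = wl6,
                                                   mua = rep(0.02, 6)))
  full <- stage3(sim$meas, prior, sim$basis, 0.3, cfg6)
  keep <- wl6[c(2, 5)]
  sub_meas <- validate_reflectance_map(
    sim$meas[sim$meas$wavelength_nm %in% keep, ])
  sub_prior <- list(scattering = prior$scattering, beta = 1,
                    top_mua = prior$top_mua[prior$top_mua$wavelength_nm %in% keep, ])
  sub_basis <- sim$basis[sim$basis$wavelength_nm %in% keep, ]
  sub <- stage3(sub_meas, sub_prior,
                chromophore_basis(sub_basis$wavelength_nm,
                                  sub_basis$mua_per_unit),
                0.3, cfg6)
  expect_equal(sub$musp, full$musp[full$wavelength_nm %in% keep])
})

test_that("stage 4 recovers the top absorption given exact priors, robust to the start", {
  mua_t <- c(0.10, 0.09, 0.08, 0.085, 0.09, 0.095)
  sim <- make_two_layer_sim(mua_t)
  prior <- list(scattering = list(top = sim$pl_t, bottom = sim$pl_b),
                beta = 1,
                top_mua = tibble::tibble(wavelength_nm = wl6, mua = mua_t),
                bottom_musp = tibble::tibble(wavelength_nm = wl6,
                                             musp = musp_at(sim$pl_b, wl6)))
  s4 <- stage4(sim$meas, prior, sim$basis, 0.3, cfg6)
  expect_rel_equal(s4$mua, mua_t, 1e-3)
  # perturbing the initial guess by +/-20% leaves the optimum unchanged
  for (f in c(0.8, 1.2)) {
    prior_p <- prior
    prior_p$top_mua$mua <- mua_t * f
    s4p <- stage4(sim$meas, prior_p, sim$basis, 0.3, cfg6)
    expect_equal(s4p$mua, s4$mua, tolerance = 1e-4)
  }
  expect_false(any(s4$at_floor))
})

test_that("the full staged inversion validates inputs and is deterministic", {
  wl4 <- analysis_wavelengths(4)
  cfg4 <- stage_config(band1 = c(0, 0.02), band2 = c(0.3, 0.32),
                       n_wavelengths = 4)
  spec <- phantom_spec()
  fr <- c(0, 0.01, 0.02, 0.06, 0.15, 0.3, 0.32)
  sim <- suppressWarnings(simulate_phantom(spec, wl4, fr, noise = NULL))
  inv1 <- run_staged_inversion(sim$measurement, sim$basis, 0.3, cfg4)
  inv2 <- run_staged_inversion(sim$measurement, sim$basis, 0.3, cfg4)
  expect_identical(tidy(inv1), tidy(inv2))
  expect_identical(glance(inv1), glance(inv2))
  expect_true(all(tidy(inv1)$value >= 0))
  expect_s3_class(glance(inv1), "tbl_df")

  # a missing stage-3 frequency is reported with stage and frequency
  fr_m <- setdiff(fr, 0.15)
  sim_m <- suppressWarnings(simulate_phantom(spec, wl4, fr_m, noise = NULL))
  err <- tryCatch(
    run_staged_inversion(sim_m$measurement, sim_m$basis, 0.3, cfg4),
    error = function(e) e)
  expect_s3_class(err, "sfdlayers_input_error")
  expect_match(conditionMessage(err), "stage 3")
  expect_match(conditionMessage(err), "0.15")
})
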