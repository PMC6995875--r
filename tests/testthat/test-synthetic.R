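test_that("power-law scattering evaluates to A at the reference wavelength", {
  pl <- power_law_scattering(1.1, 1.3)
  expect_equal(musp_at(pl, 750), 1.1)
  expect_equal(musp_at(pl, c(450, 1000)),
               1.1 * (c(450, 1000) / 750)^(-1.3))
})

test_that("the default top-absorption preset hits the 600-850 nm double-hump range", {
  ap <- top_absorption_preset("naphthol")
  expect_true(mua_at(ap, 700) >= 0.01 && mua_at(ap, 700) <= 0.02)
  # two local maxima inside 600-850 nm
  wl <- seq(600, 850, by = 1)
  v <- mua_at(ap, wl)
  d <- diff(sign(diff(v)))
  expect_gte(sum(d == -2), 2)
})

test_that("the high-absorption preset stays above the recoverability floor in 600-800 nm", {
  ap <- top_absorption_preset("naphthol_high")
  wl <- seq(600, 800, by = 5)
  expect_true(all(mua_at(ap, wl) >= 0.075))
  expect_true(all(mua_at(ap, seq(450, 1000, by = 5)) <= 0.2))
})

test_that("build_media is deterministic and carries exact ground truth", {
  wl <- analysis_wavelengths(8)
  spec <- phantom_spec(beta = 1)
  m1 <- suppressWarnings(build_media(spec, wl))
  m2 <- suppressWarnings(build_media(spec, wl))
  expect_identical(attr(m1, "truth"), attr(m2, "truth"))
  tr <- attr(m1, "truth")
  # beta = 1: bottom absorption equals the basis shape exactly
  expect_equal(dplyr::filter(tr, layer == "bottom")$mua,
               attr(m1, "basis")$mua_per_unit)
  expect_equal(dplyr::filter(tr, layer == "top")$musp,
               musp_at(spec$top_scattering, wl))
  expect_error(build_media(spec, c(400, 700)),
               class = "sfdlayers_input_error")
  expect_warning(
    build_media(phantom_spec(top_scattering = power_law_scattering(3, 1)),
                c(700, 750)),
    class = "sfdlayers_range_warning")
})

test_that("multiplicative noise honors its contracted distribution", {
  rd <- rep(0.5, 1000)
  noisy <- sfdlayers:::apply_noise(rd, noise_model(0.01, 0, seed = 42))
  rel_sd <- stats::sd(noisy / rd - 1)
  expect_gte(rel_sd, 0.009)
  expect_lte(rel_sd, 0.011)
  # reproducible from the seed
  again <- sfdlayers:::apply_noise(rd, noise_model(0.01, 0, seed = 42))
  expect_identical(noisy, again)
  # clipped to [0, 1]
  clipped <- sfdlayers:::apply_noise(rep(0.999, 200),
                                     noise_model(0.05, 0, seed = 1))
  expect_true(all(clipped <= 1 & clipped >= 0))
})

test_that("three-phase demodulation identities hold", {
  expect_equal(demodulate_three_phase(5, 5, 5), 0)
  ph <- c(0, 2 * pi / 3, 4 * pi / 3)
  i <- 1 + 0.3 * cos(ph)
  expect_equal(demodulate_three_phase(i[1], i[2], i[3]), 0.3,
               tolerance = 1e-12)
  # carrier-phase invariance
  set.seed(3)
  for (phi0 in stats::runif(100, 0, 2 * pi)) {
    i <- 2.4 + 0.7 * cos(phi0 + ph)
    expect_lt(abs(demodulate_three_phase(i[1], i[2], i[3]) - 0.7), 1e-12)
  }
  expect_error(demodulate_three_phase(1, NA, 2),
               class = "sfdlayers_input_error")
})

test_that("three-phase emulation reproduces the direct reflectance map", {
  wl <- c(600, 800)
  media <- suppressWarnings(build_media(phantom_spec(), wl))
  fx <- c(0, 0.1, 0.3)
  direct <- simulate_measurement(media, fx, noise = NULL)
  demod <- simulate_measurement(media, fx, noise = NULL, demodulate = TRUE,
                                phase0 = 1.1)
  expect_lt(max(abs(direct$rd - demod$rd)), 1e-12)
  # noiseless path equals the plain forward map
  fwd <- reflectance_map(media, fx)
  expect_identical(direct$rd, fwd$rd)
})

test_that("simulated measurements are reproducible from the seed", {
  wl <- c(600, 800)
  media <- suppressWarnings(build_media(phantom_spec(), wl))
  fx <- c(0, 0.1)
  a <- simulate_measurement(media, fx, noise_model(seed = 9))
  b <- simulate_measurement(media, fx, noise_model(seed = 9))
  expect_identical(a$rd, b$rd)
  c <- simulate_measurement(media, fx, noise_model(seed = 10))
  expect_false(identical(a$rd, c$rd))
})
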