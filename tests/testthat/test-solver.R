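test_that("two identical layers collapse to the homogeneous result", {
  cases <- list(c(0.01, 1.0), c(0.1, 0.7), c(0.2, 1.3))
  for (p in cases) {
    for (fx in c(0, 0.07, 0.3)) {
      two <- layered_medium(list(optical_layer(p[1], p[2]),
                                 optical_layer(p[1], p[2])), c(0.8, Inf))
      one <- layered_medium(list(optical_layer(p[1], p[2])), Inf)
      expect_lt(abs(solve_layered_reflectance(two, fx) -
                      solve_layered_reflectance(one, fx)), 1e-6)
    }
  }
})

test_that("a vanishing top layer reduces to the bottom-only result", {
  thin <- layered_medium(list(optical_layer(0.05, 0.6),
                              optical_layer(0.1, 1.0)), c(1e-6, Inf))
  bottom <- layered_medium(list(optical_layer(0.1, 1.0)), Inf)
  for (fx in c(0, 0.1, 0.4)) {
    expect_lt(abs(solve_layered_reflectance(thin, fx) -
                    solve_layered_reflectance(bottom, fx)), 1e-4)
  }
})

test_that("solver agrees with the diffusion closed form in the diffusive regime", {
  # high albedo, low frequency: SDA is a valid independent oracle to ~10%
  for (p in list(c(0.01, 1.0), c(0.005, 1.0), c(0.01, 1.3))) {
    m <- layered_medium(list(optical_layer(p[1], p[2])), Inf)
    for (fx in c(0, 0.05, 0.1)) {
      rs <- solve_layered_reflectance(m, fx)
      ro <- sda_reflectance(p[1], p[2], 1.4, fx)
      expect_lt(abs(rs - ro) / ro, 0.1)
    }
  }
})

test_that("reflectance decreases when absorption increases in either layer", {
  base <- fig3_medium()
  for (fx in c(0, 0.05, 0.15, 0.4)) {
    r0 <- solve_layered_reflectance(base, fx)
    up_t <- fig3_medium(mua_t = 0.011)
    up_b <- fig3_medium(mua_b = 0.11)
    expect_lt(solve_layered_reflectance(up_t, fx), r0)
    expect_lt(solve_layered_reflectance(up_b, fx), r0)
  }
})

test_that("ninth-order expansion is converged against eleventh order", {
  cfg9 <- shef_config(9); cfg11 <- shef_config(11)
  for (p in list(c(0.01, 0.5), c(0.2, 1.3))) {
    m <- layered_medium(list(optical_layer(p[1], p[2]),
                             optical_layer(0.05, 1.0)), c(0.3, Inf))
    for (fx in c(0, 0.15, 0.5)) {
      r9 <- solve_layered_reflectance(m, fx, cfg9)
      r11 <- solve_layered_reflectance(m, fx, cfg11)
      expect_lt(abs(r9 - r11) / r11, 0.01)
    }
  }
})

test_that("an absorption-free index-matched medium conserves energy at fx = 0", {
  m <- layered_medium(list(optical_layer(0, 1.0, n = 1)), Inf, n_ambient = 1)
  expect_equal(solve_layered_reflectance(m, 0), 1, tolerance = 1e-3)
})

test_that("repeat solves are bitwise identical", {
  m <- fig3_medium()
  r1 <- solve_layered_reflectance(m, 0.23)
  r2 <- solve_layered_reflectance(m, 0.23)
  expect_identical(r1, r2)
})

test_that("reflectance maps are grid-complete, bounded and order-independent", {
  media <- list(fig3_medium(), fig3_medium(mua_t = 0.05))
  fx <- c(0, 0.1, 0.3)
  map <- reflectance_map(media, fx, wavelengths = c(500, 700))
  expect_s3_class(map, "reflectance_map")
  expect_equal(nrow(map), 6)
  expect_true(all(map$rd >= 0 & map$rd <= 1))
  # single cell equals the scalar solve
  one <- reflectance_map(list(fig3_medium()), 0.1, wavelengths = 700)
  expect_identical(one$rd, solve_layered_reflectance(fig3_medium(), 0.1))
  # permuting the frequency grid then sorting yields the identical map
  map_perm <- reflectance_map(media, rev(fx), wavelengths = c(500, 700))
  expect_equal(dplyr::arrange(tibble::as_tibble(map_perm),
                              wavelength_nm, fx_per_mm)$rd,
               map$rd)
  expect_error(reflectance_map(media, fx, wavelengths = 700),
               class = "sfdlayers_input_error")
})
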