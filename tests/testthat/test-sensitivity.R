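test_that("absorption sensitivity is nonpositive at every frequency", {
  fx <- seq(0, 0.4, by = 0.05)
  for (layer in 1:2) {
    s <- sensitivity_curve(fig3_medium(), layer, "mua", fx)
    expect_true(all(s$dRd_dp <= 0))
    expect_true(all(is.finite(s$dRd_dp)))
  }
})

test_that("central differences are step-converged", {
  fx <- c(0, 0.06, 0.15, 0.3)
  s1 <- sensitivity_curve(fig3_medium(), 2, "musp", fx, rel_step = 0.01)
  s2 <- sensitivity_curve(fig3_medium(), 2, "musp", fx, rel_step = 0.005)
  expect_rel_equal(s1$dRd_dp, s2$dRd_dp, 0.01)
})

test_that("peak_frequency returns the argmax with ties toward lower fx", {
  fx <- seq(0, 0.5, by = 0.01)
  bump <- tibble::tibble(fx_per_mm = fx, dRd_dp = -exp(-(fx - 0.2)^2 / 0.005),
                         parameter_id = "synthetic")
  expect_equal(peak_frequency(bump), 0.2)
  tie <- tibble::tibble(fx_per_mm = c(0, 0.1, 0.2), dRd_dp = c(1, 2, 2),
                        parameter_id = "tie")
  expect_equal(peak_frequency(tie), 0.1)
  zero <- tibble::tibble(fx_per_mm = fx, dRd_dp = 0, parameter_id = "z")
  expect_error(peak_frequency(zero), class = "sfdlayers_undefined_peak_error")
})

test_that("decay_frequency matches the closed form and is scale invariant", {
  fx <- seq(0, 0.5, by = 0.01)
  curve <- tibble::tibble(fx_per_mm = fx, dRd_dp = exp(-fx / 0.05),
                          parameter_id = "exp")
  # exp decay crosses 1/10 at 0.05 * ln(10) = 0.1151 -> first grid point 0.12
  expect_equal(decay_frequency(curve), 0.12)
  scaled <- curve; scaled$dRd_dp <- -7.3 * scaled$dRd_dp
  expect_equal(decay_frequency(scaled), decay_frequency(curve))
  flat <- tibble::tibble(fx_per_mm = fx, dRd_dp = 1 + 0 * fx,
                         parameter_id = "flat")
  expect_equal(decay_frequency(flat), Inf)
  no0 <- curve[-1, ]
  expect_error(decay_frequency(no0), class = "sfdlayers_input_error")
})

test_that("bottom-scattering sensitivity peaks at an interior frequency near 0.06", {
  fx <- seq(0, 0.25, by = 0.01)
  peaks <- vapply(c(0.4, 0.7, 1.0, 1.3, 1.6), function(r) {
    peak_frequency(sensitivity_curve(fig3_medium(musp_t = r), 2, "musp", fx))
  }, 0)
  expect_true(all(peaks > 0))            # distinct peak at nonzero fx
  expect_true(all(abs(peaks - 0.06) <= 0.01 + 1e-9))
})

test_that("top-scattering peak frequency rises with the top/bottom scattering ratio", {
  fx <- seq(0, 0.25, by = 0.01)
  peaks <- vapply(c(0.4, 1.0, 1.6), function(r) {
    peak_frequency(sensitivity_curve(fig3_medium(musp_t = r), 1, "musp", fx))
  }, 0)
  expect_true(all(diff(peaks) > 0))
  expect_true(peaks[1] <= 0.07)   # bottom-dominant contrast: low peak
  expect_gte(peaks[3], 0.14)      # top-dominant contrast: high peak
})

test_that("low-frequency absorption sensitivity favors the bottom layer", {
  fx <- seq(0, 0.1, by = 0.01)
  sb <- sensitivity_curve(fig3_medium(), 2, "mua", fx)
  st <- sensitivity_curve(fig3_medium(), 1, "mua", fx)
  expect_gt(max(abs(sb$dRd_dp)) / max(abs(st$dRd_dp)), 3)
})

test_that("sensitivity input validation", {
  expect_error(sensitivity_curve(fig3_medium(), 3, "mua", c(0, 0.1)),
               class = "sfdlayers_input_error")
  expect_error(sensitivity_curve(fig3_medium(), 1, "mua", c(0, 0.1),
                                 rel_step = 0.5),
               class = "sfdlayers_input_error")
})
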