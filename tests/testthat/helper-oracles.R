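# Independent oracles, deliberately implemented without touching the
# package's solver internals.

# Standard diffusion approximation (SDA) spatial-frequency reflectance for a
# homogeneous semi-infinite medium: effective attenuation
# sqrt(3*mua*mutr + (2*pi*fx)^2) with the partial-current boundary constant
# A = (1 - Reff) / (2 (1 + Reff)), Reff = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2.
sda_reflectance <- function(mua, musp, n, fx) {
  mutr <- mua + musp
  ap <- musp / mutr
  mueffp <- sqrt(3 * mua * mutr + (2 * pi * fx)^2)
  Reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - Reff) / (2 * (1 + Reff))
  3 * A * ap / ((mueffp / mutr + 1) * (mueffp / mutr + 3 * A))
}

# Azimuthally symmetric P_N streaming matrix (m = 0 block) from the
# three-term Legendre recursion: <f_{l'} | mu | f_l> couples l and l+1 with
# a_l = (l+1) / sqrt((2l+1)(2l+3)).
pn_m0_streaming <- function(order) {
  M <- matrix(0, order + 1, order + 1)
  for (l in 0:(order - 1)) {
    a <- (l + 1) / sqrt((2 * l + 1) * (2 * l + 3))
    M[l + 1, l + 2] <- a
    M[l + 2, l + 1] <- a
  }
  M
}

# Two-layer test medium in the sensitivity-analysis configuration.
fig3_medium <- function(mua_t = 0.01, musp_t = 1, mua_b = 0.1, musp_b = 1,
                        d = 0.3) {
  layered_medium(list(optical_layer(mua_t, musp_t),
                      optical_layer(mua_b, musp_b)),
                 thicknesses = c(d, Inf))
}

# Frequency grid that contains every band the staged inversion consumes,
# without the full instrument grid (keeps unit tests fast).
inversion_frequencies <- function() {
  sort(unique(c(seq(0, 0.1, by = 0.02), seq(0.3, 0.4, by = 0.02),
                0.01, 0.06, 0.15)))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
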