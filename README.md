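# sfdlayers

Forward modeling and staged inversion of multispectral **spatial
frequency-domain spectroscopy (SFDS)** measurements of two-layer turbid
media — recovering the absorption (µa) and reduced scattering (µs′) spectra
of both a thin superficial layer and the semi-infinite base beneath it.

SFDS projects sinusoidal patterns of spatial frequency *fx* onto a sample
and measures the demodulated AC diffuse reflectance Rd(λ, fx). Because high
frequencies weight superficial photon paths and low frequencies weight deep
ones, a multi-frequency, multi-wavelength reflectance map encodes layered
structure. The regime of interest here — superficial layers thinner than
the transport mean free path l\* = 1/(µa + µs′), e.g. 90–300 µm films — is
exactly where the standard diffusion approximation breaks down, so the
forward model is a deterministic radiative-transport solver:

* **Forward (SHEF-N):** an order-N spherical-harmonic expansion of the
  radiance with Fourier decomposition in the transverse coordinate, giving
  (N+1)² coupled depth equations per layer (N = 9 by default). Layers are
  eigendecomposed into exponential depth modes; Marshak half-range boundary
  conditions with Fresnel internal reflection close the system at the
  surface, flux-moment continuity at interior interfaces, decaying modes
  only in the semi-infinite base. Delta-M scaling of the Henyey–Greenstein
  phase function (g = 0.8) keeps order-9 results converged to a few 10⁻³.
* **Sensitivity:** finite-difference curves ∂Rd/∂p over the frequency grid
  for each layer's µa and µs′, plus their peak and decade-decay frequencies
  — the structure that motivates which frequencies each inversion stage
  uses.
* **Inversion (four stages):** (1) per-layer scattering power laws
  µs′ = A(λ/750)⁻ᵇ from a low band (0–0.1 mm⁻¹, bottom-weighted) and a high
  band (0.3–0.4 mm⁻¹, top-weighted) via homogeneous fits; (2) bottom-layer
  absorption as β × a known basis shape plus a free top-layer µa per
  wavelength, fit at fx = 0.01, 0.02 mm⁻¹; (3) per-wavelength refinement of
  bottom µs′ at fx = 0.06, 0.15 mm⁻¹; (4) per-wavelength refinement of top
  µa. Deterministic, bounded least squares throughout.
* **Synthetic phantoms:** power-law scattering plus Gaussian-peak
  absorption spectra emulating dyed two-layer siloxane phantoms, seeded
  measurement noise, and three-phase demodulation emulation — so the whole
  pipeline is testable with no instrument data.

See the methods vignette (`vignettes/layered-sfd-inversion.Rmd`) for the
model, assumptions, numerical choices and limitations.

## Worked example

Simulate a noisy two-layer phantom measurement (top: A = 1.1, b = 1.3,
dye-like µa; bottom: A = 1.0, b = 1.2, β = 1 × a hemoglobin-like basis;
300 µm top layer), then run the staged inversion. An 8-wavelength grid
keeps this under two minutes; the shipped experiments use 32.

```r
library(sfdlayers)
wl    <- analysis_wavelengths(8)
freqs <- sort(unique(c(seq(0, 0.1, 0.02), seq(0.3, 0.4, 0.02), 0.01, 0.06, 0.15)))
sim   <- simulate_phantom(phantom_spec(), wl, freqs, noise = noise_model(seed = 7))
inv   <- run_staged_inversion(sim$measurement, sim$basis, thickness = 0.3,
                              stage_config(n_wavelengths = 8))
inv
#> <sfd_inversion>
#>   wavelengths: 8 (450-1000 nm), top thickness 0.3 mm
#>   stage 1: top musp' = 1.08*(lambda/750)^-1.31, bottom A=1.02 b=1.28
#>   stage 2: beta = 0.9906 (9 unknowns)
#>   stage 3: bottom musp' refined per wavelength (0 fallback)
#>   stage 4: top mua refined per wavelength (0 at floor)
```

The stage-1 power laws land within a few percent of the generator's truth
(top 1.1/1.3, bottom 1.0/1.2), and β = 0.99 against a true value of 1 —
the bottom-layer absorption spectrum is recovered to about 1% here.
`glance()` gives one-row fit diagnostics, `tidy()` the recovered spectra in
long form, and `autoplot()` plots maps, sensitivity curves and recovered
spectra:

```r
glance(inv)
#> # A tibble: 1 × 9
#>    beta stage1_rss_band1 stage1_rss_band2 stage1_iter stage2_rss stage2_iter ...
#> 1 0.991           0.0123          0.00238          11    0.00300           7

tidy(inv, stages = 3:4)
#> # A tibble: 16 × 5
#>   wavelength_nm layer  property value stage
#> 1          450  bottom musp     1.94      3
#> 2          529. bottom musp     1.58      3
#> ...
```

A command-line interface wraps the same functions for shell use
(`inst/cli/sfdlayers`): `simulate`, `invert`, `forward` and `sensitivity`
subcommands reading YAML configs and writing CSV/JSON artifacts; every run
echoes its effective configuration next to its outputs.

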