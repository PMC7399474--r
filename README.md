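# rgbsfdi

Multispectral **spatial frequency domain imaging (SFDI)** with consumer RGB
hardware, in R.

SFDI projects sinusoidal light patterns at several spatial frequencies onto
tissue and measures how strongly each frequency's modulation survives in the
diffusely reflected light. Because absorption and scattering attenuate the
modulation differently across frequency, per-pixel maps of the absorption
coefficient μa and the reduced scattering coefficient μs′ (both mm⁻¹) can be
recovered — the raw material for chromophore quantification (hemoglobin
species, melanin, carotenoids) in skin. Low-cost SFDI systems built from an
RGB LED projector and a color CMOS camera nominally provide only three wide
spectral bands, but the spectral overlap between one LED and a *different*
color channel's filter yields usable extra "cross-channel" bands (e.g. the
wide green LED seen through the blue or red filter) at no hardware cost.

This package implements the complete processing chain for such a system,
plus a synthetic instrument so the whole pipeline runs and is tested without
hardware:

- **Forward model** — white Monte Carlo photon transport in a semi-infinite
  turbid medium (scattering only; absorption applied afterwards by
  Beer–Lambert weighting of recorded pathlengths, `exp(-μa·L)`), Hankel
  transform to the spatial frequency domain, tabulation over a (μa, μs′, fx)
  grid, and a diffusion-approximation closed form
  `Rd = 3Aa′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A))` as an independent oracle.
- **SFDI core** — sinusoidal pattern generation with projector gamma
  pre-compensation, three-phase demodulation
  `MAC = (√2/3)·√((I₁−I₂)² + (I₂−I₃)² + (I₃−I₁)²)`, and calibration against
  a reference phantom `Rd = (MAC/MAC_ref)·Rd_ref` (source intensity and
  system MTF cancel in the ratio).
- **Inversion** — per-pixel Nelder–Mead fit of (μa, μs′) minimizing the
  squared misfit between measured and tabulated Rd(fx) (compiled, ~10⁵
  pixel fits per second).
- **Spectral bands** — LED×filter band responsivities, weighted-average
  band centers and FWHM, cross-channel selection, two-point wavelength
  calibration, and band-averaged emulation of continuous spectra.
- **Synthetic instrument & validation** — a gamma-distorting projector and
  noisy 8-bit auto-exposing camera, the 16-phantom Intralipid/India-ink
  validation grid (μs′(625 nm) 0.5–2.5, μa(625 nm) 0.025–0.25 mm⁻¹,
  μs′(λ) = aλ⁻ᵇ), and the phantom study comparing FOV-averaged SFDI
  estimates against band-emulated spectroscopic ground truth with linear
  regression statistics.

## Worked example

```r
library(rgbsfdi)

# 1. tabulate the forward model (scaled down for the example)
tab <- build_table(
  mu_a_grid       = exp(seq(log(0.005), log(0.5), length.out = 12)),
  mu_s_prime_grid = exp(seq(log(0.3),   log(5),   length.out = 8)),
  fx_grid = c(0, 0.0333, 0.05, 0.1), n_photons = 1e5, seed = 42)

# 2. simulate a phantom acquisition (5 bands x 4 fx x 3 phases = 60 frames)
inst <- instrument_model()                      # gamma 2.2, sigma = 1 count
ref  <- phantom_spec(1.5, 0.05, id = "reference")
ph   <- phantom_spec(2.0, 0.10, id = "ph1")
fx   <- c(0, 0.0333, 0.05, 0.1)
dir  <- tempfile()
ra <- simulate_acquisition(ref, inst, fx, tab, seed = 1, dir = dir,
                           role = "reference")
pa <- simulate_acquisition(ph,  inst, fx, tab, seed = 2, dir = dir)

# 3. demodulate, calibrate, invert per pixel
maps <- process_acquisition(rbind(pa$manifest, ra$manifest), tab, fx,
                            ref, inst$bands,
                            config = inversion_config(fx_subset = c(0, 0.05, 0.1)))
maps$GR
#> property_map 64x64: FOV mu_a = 0.1002, mu_s' = 2.296 mm^-1 (100.0% converged)
```

The phantom was generated with μa = 0.10 mm⁻¹ (flat ink spectrum) and
μs′(625 nm) = 2.0 mm⁻¹; at the GR band center (558 nm) the power law gives
μs′ = 2.29 mm⁻¹, so the fitted field-of-view means above recover the truth
to a fraction of a percent through the full simulated optical chain.

The full validation study mirrors the 16-phantom × 5-band comparison:

```r
study <- run_phantom_study(tab, seed = 7, noise_sigma = 1)
study
#> phantom_study: 160 comparison rows
#>   mu_a:      regression_result: slope 1.0018, intercept -8.523e-05, R^2 = 1.0000, RMSE = 0.000491 (n = 80)
#>   mu_s_prime:regression_result: slope 1.0024, intercept -0.004054, R^2 = 1.0000, RMSE = 0.005648 (n = 80)
```

(These synthetic R² values exceed what is achievable on physical hardware,
whose additional instrument noise the simulator deliberately omits.)

## Command line

```sh
Rscript inst/cli/rgbsfdi mc-table --out tab.json --seed 1 --photons 1000000
Rscript inst/cli/rgbsfdi characterize-bands --led-b ledB.csv ... --out-table bands.csv
Rscript inst/cli/rgbsfdi simulate --table tab.json --out-dir frames --seed 1 --phantom-grid
Rscript inst/cli/rgbsfdi process  --manifest frames/manifest.csv --table tab.json --out-dir out
Rscript inst/cli/rgbsfdi validate --table tab.json --seed 1 --out-dir study
```

## Vignette

`vignettes/methods.Rmd` documents the model and its assumptions, every
tunable parameter with units and defaults, what the synthetic instrument
does and does not emulate, and the numerical design choices.
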