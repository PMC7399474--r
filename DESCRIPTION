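Package: rgbsfdi
Title: Multispectral Spatial Frequency Domain Imaging with RGB Cross-Channel Bands
Version: 0.1.0
Authors@R:
    person("SFDI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multispectral spatial frequency domain
    imaging (SFDI) built around consumer RGB projector/camera hardware.
    Covers sinusoidal pattern generation with projector gamma
    pre-compensation, three-phase demodulation to AC modulation amplitude,
    calibration against a reference phantom of known optical properties,
    a white Monte Carlo forward model of spatially modulated diffuse
    reflectance (with a diffusion-approximation closed form as an
    independent oracle), and per-pixel Nelder-Mead inversion for absorption
    and reduced scattering coefficient maps. Spectral band tooling builds
    LED-by-filter cross-channel responsivities, computes weighted band
    centers and FWHM, and emulates band-averaged values from continuous
    spectra. A synthetic instrument simulates the full optical chain
    (gamma-distorting projector, noisy 8-bit camera) and an
    Intralipid/India-ink phantom grid so the whole pipeline is testable
    end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
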