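# Synthetic optical chain: gamma-distorting projector -> sample diffuse
# reflectance (forward table) -> noisy 8-bit quantizing camera.  Emulates
# the physical instrument closely enough that the whole processing pipeline
# (demodulate -> calibrate -> invert) is testable end to end at desk scale.

#' Synthetic LED emission curves (B, G, R)
#'
#' Gaussian stand-ins for the projector LED spectra of a consumer RGB
#' device: narrow blue (458 nm) and red (628 nm) LEDs and a wide green LED
#' (536 nm, sigma 25 nm).  The wide green emission is what makes the GB
#' and GR cross-channel bands usable.  These are synthetic curves shaped
#' to the qualitative pattern of a characterized consumer projector, not
#' measured data.
#'
#' @param grid Wavelength grid (nm).
#' @return Named list of `spectrum_curve`s: `B`, `G`, `R`.
#' @export
default_led_curves <- function(grid = default_wavelength_grid()) {
  gauss <- function(mu, sigma) {
    spectrum_curve(grid, exp(-(grid - mu)^2 / (2 * sigma^2)))
  }
  list(B = gauss(458, 12), G = gauss(536, 25), R = gauss(628, 10))
}

#' Synthetic camera color-filter transmission curves (B, G, R)
#'
#' Gaussian stand-ins for the Bayer filter transmissions of a consumer
#' CMOS camera (broad, strongly overlapping).  Synthetic, not measured.
#'
#' @param grid Wavelength grid (nm).
#' @return Named list of `spectrum_curve`s: `B`, `G`, `R`.
#' @export
default_filter_curves <- function(grid = default_wavelength_grid()) {
  gauss <- function(mu, sigma) exp(-(grid - mu)^2 / (2 * sigma^2))
  # the green Bayer filter transmits appreciably in the blue (its short-
  # wavelength shoulder), which is what makes the BG cross-channel band
  # moderately strong on real hardware
  list(B = spectrum_curve(grid, gauss(480, 35)),
       G = spectrum_curve(grid, gauss(536, 30) + 0.25 * gauss(470, 25)),
       R = spectrum_curve(grid, gauss(600, 35)))
}

#' The nine synthetic bands, or the five selected usable ones
#'
#' Builds the LED x filter band set from the synthetic curves and, for
#' `default_bands()`, applies the standard selection: the three primary
#' bands plus the usable cross-channels (GB, GR).
#'
#' @return Named list of `band_responsivity` objects.
#' @export
default_band_set <- function() {
  band_set(default_led_curves(), default_filter_curves())
}

#' @rdname default_band_set
#' @export
default_bands <- function() {
  bands <- default_band_set()
  bands[select_bands(bands)]
}

#' Tissue-simulating phantom specification
#'
#' A homogeneous Intralipid/India-ink phantom: reduced scattering follows
#' the power law `mu_s'(lambda) = a lambda^-b` (lambda in nm) and
#' absorption follows a spectral template scaled by the ink concentration,
#' both anchored at 625 nm.
#'
#' @param mu_s_prime_625 Reduced scattering at 625 nm (mm^-1).
#' @param mu_a_625 Absorption at 625 nm (mm^-1).
#' @param b Scattering power-law exponent (default 1.2, Intralipid-like);
#'   `a` is solved from the 625-nm anchor.
#' @param absorber_template `spectrum_curve` of the absorber's spectral
#'   shape; `NULL` means flat (India ink is a near-neutral absorber).
#' @param id Phantom identifier.
#' @param intralipid_pct,ink_mg_per_l Nominal concentrations (metadata).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(mu_s_prime_625, mu_a_625, b = 1.2,
                         absorber_template = NULL, id = "phantom",
                         intralipid_pct = NA_real_, ink_mg_per_l = NA_real_) {
  stopifnot(mu_s_prime_625 > 0, mu_a_625 >= 0, b >= 0)
  structure(list(id = id,
                 a = mu_s_prime_625 * 625^b, b = b,
                 mu_s_prime_625 = mu_s_prime_625, mu_a_625 = mu_a_625,
                 absorber_template = absorber_template,
                 intralipid_pct = intralipid_pct,
                 ink_mg_per_l = ink_mg_per_l),
            class = "phantom_spec")
}

#' The 16-phantom validation grid
#'
#' Four Intralipid concentrations (0.5, 1, 1.5, 2 %) crossed with four
#' India-ink concentrations (13, 27, 40, 53 mg/L).  Measured anchor values
#' span 0.5-2.5 mm^-1 for `mu_s'(625)` and 0.025-0.25 mm^-1 for
#' `mu_a(625)`; intermediate levels are interpolated linearly in
#' concentration between those endpoints.
#'
#' @param b Scattering power-law exponent shared by all phantoms.
#' @return List of 16 [phantom_spec()]s with ids `S<i>A<j>`, plus
#'   attributes `scattering_level` and `absorption_level` (1-4 each).
#' @export
make_phantom_grid <- function(b = 1.2) {
  il <- c(0.5, 1, 1.5, 2)
  ink <- c(13, 27, 40, 53)
  musp625 <- 0.5 + (il - il[1]) / (il[4] - il[1]) * (2.5 - 0.5)
  mua625 <- 0.025 + (ink - ink[1]) / (ink[4] - ink[1]) * (0.25 - 0.025)
  specs <- list()
  slev <- alev <- integer(0)
  for (i in 1:4) {
    for (j in 1:4) {
      specs[[length(specs) + 1L]] <-
        phantom_spec(musp625[i], mua625[j], b = b,
                     id = sprintf("S%dA%d", i, j),
                     intralipid_pct = il[i], ink_mg_per_l = ink[j])
      slev <- c(slev, i); alev <- c(alev, j)
    }
  }
  attr(specs, "scattering_level") <- slev
  attr(specs, "absorption_level") <- alev
  specs
}

#' Optical properties of a phantom at one wavelength
#'
#' @param spec A [phantom_spec()].
#' @param lambda Wavelength in nm, within 380-720.
#' @param g,n Anisotropy and refractive index to attach.
#' @return An [optical_properties()] object.
#' @export
phantom_properties <- function(spec, lambda, g = 0.8, n = 1.4) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (lambda < 380 || lambda > 720) {
    stop("lambda = ", lambda, " nm outside the supported 380-720 nm range")
  }
  musp <- spec$a * lambda^(-spec$b)
  tmpl <- spec$absorber_template
  mua <- if (is.null(tmpl)) {
    spec$mu_a_625
  } else {
    t625 <- approx(tmpl$wavelengths, tmpl$values, xout = 625)$y
    tl <- approx(tmpl$wavelengths, tmpl$values, xout = lambda)$y
    if (is.na(tl) || is.na(t625) || t625 <= 0) {
      stop("absorber template does not cover lambda and 625 nm")
    }
    spec$mu_a_625 * tl / t625
  }
  optical_properties(mua, musp, g = g, n = n)
}

#' Synthetic instrument model
#'
#' @param bands Named list of selected `band_responsivity` objects
#'   (default: the five usable synthetic bands).
#' @param gamma Projector gamma exponent (> 0; 2.2 typical, 1 = linear).
#' @param noise_sigma Additive Gaussian camera noise, in 8-bit counts.
#' @param pixel_pitch Projected pixel pitch at the sample plane (mm/px).
#' @param width,height Frame size in pixels.
#' @param dc_level,ac_level Pattern levels (fractions of full scale).
#' @param apply_pregamma Pre-compensate patterns for the projector gamma
#'   (the pipeline's normal operating mode).
#' @param auto_exposure Adjust exposure per band so the brightest frame
#'   peaks near `target_peak` counts, as done on the physical system;
#'   the exposure factor is recorded in the manifest and divided out of
#'   the demodulated MAC before calibration.
#' @param target_peak Auto-exposure target in 8-bit counts (default 240,
#'   leaving saturation headroom).
#' @param quantize Quantize frames to 8-bit integers (disable only to
#'   study quantization-free limits; frames are still written rounded).
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(bands = default_bands(), gamma = 2.2,
                             noise_sigma = 1, pixel_pitch = 0.5,
                             width = 64, height = 64,
                             dc_level = 0.5, ac_level = 0.5,
                             apply_pregamma = TRUE, auto_exposure = TRUE,
                             target_peak = 240, quantize = TRUE) {
  stopifnot(gamma > 0, noise_sigma >= 0, target_peak > 0,
            target_peak <= 255)
  lambda0 <- vapply(bands, function(b) band_stats(b)$lambda0, numeric(1))
  structure(list(bands = bands, lambda0 = lambda0, gamma = gamma,
                 noise_sigma = noise_sigma, pixel_pitch = pixel_pitch,
                 width = as.integer(width), height = as.integer(height),
                 dc_level = dc_level, ac_level = ac_level,
                 apply_pregamma = apply_pregamma,
                 auto_exposure = auto_exposure, target_peak = target_peak,
                 quantize = quantize, bit_depth = 8L),
            class = "instrument_model")
}

band_rd <- function(table, spec, band, lambda0, fx, integration = "delta") {
  if (integration == "delta") {
    props <- phantom_properties(spec, lambda0,
                                g = table$metadata$g, n = table$metadata$n)
    lookup_rd(table, props, fx)
  } else {
    wall <- band$curve$wavelengths
    w <- wall[seq(1, length(wall), by = 5)]
    resp <- approx(wall, band$curve$values, xout = w)$y
    keep <- resp > 1e-4 * max(resp) & w >= 380 & w <= 720
    w <- w[keep]; resp <- resp[keep]
    rd <- vapply(w, function(l) {
      props <- phantom_properties(spec, l, g = table$metadata$g,
                                  n = table$metadata$n)
      lookup_rd(table, props, fx)
    }, numeric(length(fx)))
    if (is.null(dim(rd))) rd <- matrix(rd, nrow = length(fx))
    as.vector(rd %*% resp / sum(resp))
  }
}

#' Simulate a full SFDI acquisition
#'
#' For every (band, fx, phase): generate the sinusoidal pattern, pass it
#' through the (optionally pre-compensated) gamma-distorting projector,
#' modulate the DC component by `Rd(0)` and the AC component by `Rd(fx)`
#' of the sample at the band's center wavelength, add Gaussian camera
#' noise, quantize to 8 bits and write the frame to disk.
#'
#' @param sample A [phantom_spec()].
#' @param instrument An [instrument_model()].
#' @param fx_list Spatial frequencies (mm^-1) to project.
#' @param table A [build_table()] reflectance table covering the sample.
#' @param seed Integer seed (frame noise); identical seeds give
#'   byte-identical frames.
#' @param dir Output directory for the frames.
#' @param role `"sample"` or `"reference"` (manifest bookkeeping).
#' @param format `"bmp"` (default) or `"png"`.
#' @param band_integration `"delta"` evaluates Rd at the band center
#'   wavelength; `"full"` integrates Rd(lambda) over the band
#'   responsivity (for studying band-averaging bias).
#' @return An `acquisition_set`: the manifest data frame plus the config
#'   snapshot and seed.
#' @export
simulate_acquisition <- function(sample, instrument, fx_list, table, seed,
                                 dir = tempdir(), role = "sample",
                                 format = "bmp",
                                 band_integration = "delta") {
  stopifnot(inherits(sample, "phantom_spec"),
            inherits(instrument, "instrument_model"))
  if (missing(seed)) stop("seed is mandatory")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  phases <- c(0, 120, 240)
  gcurve <- power_gamma_curve(instrument$gamma)
  rows <- list()
  for (bi in seq_along(instrument$bands)) {
    bname <- names(instrument$bands)[bi]
    rd <- band_rd(table, sample, instrument$bands[[bi]],
                  instrument$lambda0[[bi]], c(0, fx_list),
                  integration = band_integration)
    rd0 <- rd[1]
    # exposure: brightest pixel of the fx = 0 phase-0 frame is
    # (dc + ac) * rd0 of full scale; scale it to target_peak counts
    exposure <- if (instrument$auto_exposure) {
      instrument$target_peak /
        (255 * (instrument$dc_level + instrument$ac_level) * rd0)
    } else 1
    for (fi in seq_along(fx_list)) {
      for (pi in seq_along(phases)) {
        spec <- pattern_spec(fx_list[fi], phases[pi], instrument$width,
                             instrument$height, instrument$pixel_pitch,
                             instrument$dc_level, instrument$ac_level)
        pat <- make_pattern(spec)
        emitted <- if (instrument$apply_pregamma) {
          apply_gamma_device(pregamma(pat, gcurve), gcurve)
        } else {
          # uncompensated projection: the device distorts the sinusoid
          apply_gamma_device(matrix(as.integer(round(pat * 255)),
                                    nrow = nrow(pat)), gcurve)
        }
        # first-harmonic image formation: DC sees Rd(0), the modulated
        # residual sees Rd(fx)
        reflected <- instrument$dc_level * rd0 +
          (emitted - instrument$dc_level) * rd[1 + fi]
        counts <- reflected * 255 * exposure
        if (instrument$noise_sigma > 0) {
          counts <- counts + rnorm(length(counts),
                                   sd = instrument$noise_sigma)
        }
        counts <- pmin(pmax(counts, 0), 255)
        if (instrument$quantize) counts <- round(counts)
        frame <- matrix(counts, nrow = instrument$height)
        fname <- sprintf("%s_%s_f%d_p%d.%s", sample$id, bname, fi, pi,
                         format)
        fpath <- file.path(dir, fname)
        write_frame(frame, fpath)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample$id, band = bname, fx_index = fi,
          phase_index = pi, path = fpath, role = role,
          exposure = exposure, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(manifest = manifest,
                 config = list(fx = fx_list, phases = phases,
                               bands = names(instrument$bands),
                               gamma = instrument$gamma,
                               noise_sigma = instrument$noise_sigma,
                               pixel_pitch = instrument$pixel_pitch,
                               band_integration = band_integration),
                 seed = seed),
            class = "acquisition_set")
}

#' Idealized spectroscopic (SFDS-like) counterpart of a phantom
#'
#' Produces the continuous-wavelength ground truth a point spectroscopy
#' system would measure on the same sample: `Rd(fx, lambda)` on a 1-nm
#' grid over 400-700 nm, plus optical-property spectra recovered by
#' fitting each wavelength with the same inverse solver (noise-free, so
#' the fits reproduce the generating properties up to solver tolerance).
#'
#' @param sample A [phantom_spec()].
#' @param table A reflectance table tabulating every requested fx.
#' @param fx_list Spectroscopy frequencies (default 0, 0.05, 0.1, 0.15,
#'   0.2 mm^-1).
#' @param lambda_grid Wavelengths (nm), default 400-700 at 1 nm.
#' @param fit Also run the per-wavelength inverse fits (default TRUE).
#' @return List with `lambda`, `rd` (matrix lambda x fx), `mu_a_true`,
#'   `mu_s_prime_true` and (if `fit`) `mu_a_fit`, `mu_s_prime_fit`.
#' @export
simulate_sfds_spectrum <- function(sample, table,
                                   fx_list = c(0, 0.05, 0.1, 0.15, 0.2),
                                   lambda_grid = seq(400, 700, by = 1),
                                   fit = TRUE) {
  stopifnot(inherits(sample, "phantom_spec"))
  g <- table$metadata$g; n <- table$metadata$n
  props <- lapply(lambda_grid, function(l) {
    phantom_properties(sample, l, g = g, n = n)
  })
  rd <- t(vapply(props, function(p) lookup_rd(table, p, fx_list),
                 numeric(length(fx_list))))
  out <- list(lambda = lambda_grid, fx = fx_list, rd = rd,
              mu_a_true = vapply(props, `[[`, numeric(1), "mu_a"),
              mu_s_prime_true = vapply(props, `[[`, numeric(1),
                                       "mu_s_prime"))
  if (fit) {
    cfg <- inversion_config(fx_subset = fx_list)
    f <- cpp_fit_pixels(rd, log(table$mu_a_grid), log(table$mu_s_prime_grid),
                        table_fx_slice(table, fx_list),
                        c(cfg$initial_guess$mu_a,
                          cfg$initial_guess$mu_s_prime),
                        c(cfg$mu_a_bounds, cfg$mu_s_prime_bounds),
                        cfg$ftol, cfg$xtol, cfg$max_iter)
    out$mu_a_fit <- f[, 1]
    out$mu_s_prime_fit <- f[, 2]
  }
  out
}
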