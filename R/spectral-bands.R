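#' Spectrum curve on a common wavelength grid
#'
#' @param wavelengths Strictly ascending wavelengths (nm), length >= 2.
#' @param values Non-negative relative intensity / transmission.
#' @return An object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(wavelengths, values) {
  stopifnot(length(wavelengths) == length(values), length(wavelengths) >= 2)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly ascending")
  }
  if (any(values < 0)) stop("spectrum values must be >= 0")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)),
            class = "spectrum_curve")
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; wavelengths outside the original support map to 0.
#'
#' @param curve A `spectrum_curve`.
#' @param grid Target wavelengths (nm), strictly ascending.
#' @return A `spectrum_curve` on `grid`.
#' @export
resample_spectrum <- function(curve, grid = default_wavelength_grid()) {
  stopifnot(inherits(curve, "spectrum_curve"))
  v <- approx(curve$wavelengths, curve$values, xout = grid,
              yleft = 0, yright = 0)$y
  spectrum_curve(grid, v)
}

#' Default common wavelength grid: 380-720 nm at 1 nm
#' @export
default_wavelength_grid <- function() seq(380, 720, by = 1)

#' Read / write two-column spectrum CSV files
#'
#' Format: header line, columns `wavelength_nm,value`.
#'
#' @param path File path.
#' @param curve A `spectrum_curve` (writer only).
#' @return `read_spectrum_csv()` returns a `spectrum_curve`.
#' @export
read_spectrum_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("spectrum CSV needs columns 'wavelength_nm' and 'value': ", path)
  }
  spectrum_curve(d$wavelength_nm, d$value)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(curve, path) {
  stopifnot(inherits(curve, "spectrum_curve"))
  write.csv(data.frame(wavelength_nm = curve$wavelengths,
                       value = curve$values),
            path, row.names = FALSE)
  invisible(path)
}

BAND_NAMES <- c("BB", "BG", "BR", "GB", "GG", "GR", "RB", "RG", "RR")

#' Cross-channel band responsivity from an LED and a filter curve
#'
#' Pointwise product of one LED emission spectrum with one camera color
#' filter transmission; the overlap of mismatched colors (e.g. green LED
#' through the red filter) yields a cross-channel band.
#'
#' @param led,filter `spectrum_curve`s on the same wavelength grid.
#' @param name Two-letter band code, first letter the LED color, second
#'   the filter color (one of BB, BG, BR, GB, GG, GR, RB, RG, RR).
#' @param relative_strength Optional integral strength relative to the
#'   strongest band; filled in by [band_set()].
#' @return An object of class `band_responsivity`.
#' @export
cross_channel_product <- function(led, filter, name,
                                  relative_strength = NA_real_) {
  stopifnot(inherits(led, "spectrum_curve"), inherits(filter, "spectrum_curve"))
  if (!name %in% BAND_NAMES) {
    stop("band name must be one of: ", paste(BAND_NAMES, collapse = ", "))
  }
  if (length(led$wavelengths) != length(filter$wavelengths) ||
      any(led$wavelengths != filter$wavelengths)) {
    stop("LED and filter curves are on different wavelength grids; ",
         "resample both with resample_spectrum() first")
  }
  structure(list(name = name,
                 curve = spectrum_curve(led$wavelengths,
                                        led$values * filter$values),
                 relative_strength = relative_strength),
            class = "band_responsivity")
}

band_integral <- function(band) {
  w <- band$curve$wavelengths
  sum(diff(w) * (band$curve$values[-1] + band$curve$values[-length(w)]) / 2)
}

#' Build all nine LED x filter bands with relative strengths
#'
#' LED and filter sets are each normalized to their own global maximum
#' (preserving within-set intensity ratios), then multiplied pairwise.
#' `relative_strength` is each band's integral divided by the largest band
#' integral.
#'
#' @param leds Named list of `spectrum_curve`s: `B`, `G`, `R`.
#' @param filters Named list of `spectrum_curve`s: `B`, `G`, `R`.
#' @param grid Common wavelength grid for resampling.
#' @return Named list of nine `band_responsivity` objects.
#' @export
band_set <- function(leds, filters, grid = default_wavelength_grid()) {
  stopifnot(all(c("B", "G", "R") %in% names(leds)),
            all(c("B", "G", "R") %in% names(filters)))
  leds <- lapply(leds[c("B", "G", "R")], resample_spectrum, grid = grid)
  filters <- lapply(filters[c("B", "G", "R")], resample_spectrum, grid = grid)
  led_max <- max(vapply(leds, function(c) max(c$values), numeric(1)))
  fil_max <- max(vapply(filters, function(c) max(c$values), numeric(1)))
  if (led_max > 0) leds <- lapply(leds, function(c) {
    spectrum_curve(c$wavelengths, c$values / led_max)
  })
  if (fil_max > 0) filters <- lapply(filters, function(c) {
    spectrum_curve(c$wavelengths, c$values / fil_max)
  })
  bands <- list()
  for (lc in c("B", "G", "R")) {
    for (fc in c("B", "G", "R")) {
      nm <- paste0(lc, fc)
      bands[[nm]] <- cross_channel_product(leds[[lc]], filters[[fc]], nm)
    }
  }
  ints <- vapply(bands, band_integral, numeric(1))
  top <- max(ints)
  for (nm in names(bands)) {
    bands[[nm]]$relative_strength <- if (top > 0) ints[[nm]] / top else 0
  }
  bands
}

#' Weighted-average band center and FWHM
#'
#' The center is the intensity-weighted mean wavelength
#' `lambda0 = sum(lambda s) / sum(s)` (not a Gaussian fit: cross-channel
#' bands can have complex shapes).  The FWHM is the width between the
#' outermost crossings of half the peak value, linearly interpolated
#' between grid samples.
#'
#' @param band A `band_responsivity`.
#' @return A list of class `band_stats` with `lambda0` and `fwhm` (nm).
#' @export
band_stats <- function(band) {
  stopifnot(inherits(band, "band_responsivity"))
  w <- band$curve$wavelengths
  s <- band$curve$values
  if (all(s == 0)) stop("unusable band: ", band$name, " is identically zero")
  lambda0 <- sum(w * s) / sum(s)
  half <- max(s) / 2
  above <- s >= half
  cross_left <- function(i) {
    # crossing between samples i-1 (below) and i (above)
    if (i == 1L) return(w[1])
    approx(s[(i - 1):i], w[(i - 1):i], xout = half)$y
  }
  cross_right <- function(i) {
    if (i == length(s)) return(w[length(w)])
    approx(s[i:(i + 1)], w[i:(i + 1)], xout = half)$y
  }
  il <- which(above)[1]
  ir <- which(above)[sum(above)]
  fwhm <- cross_right(ir) - cross_left(il)
  structure(list(lambda0 = lambda0, fwhm = fwhm), class = "band_stats")
}

#' @export
print.band_stats <- function(x, ...) {
  cat(format_band_stats(x), "\n")
  invisible(x)
}

#' Render band stats in the conventional "lambda0 +/- FWHM/2" form
#' @param stats A `band_stats`.
#' @param digits Rounding digits.
#' @return A string like `"520 +/- 20 nm"`.
#' @export
format_band_stats <- function(stats, digits = 0) {
  sprintf("%s +/- %s nm", round(stats$lambda0, digits),
          round(stats$fwhm / 2, digits))
}

#' Select the usable spectral bands
#'
#' The three primary bands (BB, GG, RR) are always retained.  A
#' cross-channel band is added when its `relative_strength` reaches
#' `strength_threshold` (an SNR proxy) and it is not excluded by
#' `min_lambda0`: bands centered below 500 nm are dropped because blue
#' light is strongly absorbed in tissue, degrading the effective SNR.
#' The result is ordered by band center.
#'
#' @param bands List of nine `band_responsivity` from [band_set()].
#' @param strength_threshold Minimum relative integral (default 0.05).
#' @param min_lambda0 Cross-channel exclusion cutoff in nm (default 500;
#'   set to `-Inf` to disable).
#' @return Character vector of selected band names, ordered by lambda0.
#' @export
select_bands <- function(bands, strength_threshold = 0.05,
                         min_lambda0 = 500) {
  primary <- c("BB", "GG", "RR")
  keep <- character()
  l0 <- numeric()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    zero <- all(b$curve$values == 0)
    if (nm %in% primary) {
      keep <- c(keep, nm)
      l0 <- c(l0, if (zero) Inf else band_stats(b)$lambda0)
      next
    }
    if (zero || b$relative_strength < strength_threshold) next
    stats <- band_stats(b)
    if (stats$lambda0 < min_lambda0) next
    keep <- c(keep, nm)
    l0 <- c(l0, stats$lambda0)
  }
  keep[order(l0)]
}

#' Two-point wavelength calibration from reference laser lines
#'
#' Fits the exact linear pixel-to-wavelength map through two reference
#' lines of known wavelength (e.g. 532 and 650 nm laser pointers imaged
#' through a diffraction grating).
#'
#' @param line_pixels Two distinct pixel positions.
#' @param line_nm The two known wavelengths (nm).
#' @return A list of class `wavelength_calibration` with `slope`
#'   (nm/pixel), `intercept` (nm) and `reference_lines`.
#' @export
wavelength_calibrate <- function(line_pixels, line_nm) {
  stopifnot(length(line_pixels) == 2, length(line_nm) == 2)
  if (line_pixels[1] == line_pixels[2]) {
    stop("reference lines must be at distinct pixels")
  }
  if (line_nm[1] == line_nm[2]) {
    stop("reference wavelengths must be distinct")
  }
  slope <- diff(line_nm) / diff(line_pixels)
  intercept <- line_nm[1] - slope * line_pixels[1]
  structure(list(slope = slope, intercept = intercept,
                 reference_lines = data.frame(pixel = line_pixels,
                                              nm = line_nm)),
            class = "wavelength_calibration")
}

#' Apply a wavelength calibration to pixel positions
#' @param calib A `wavelength_calibration`.
#' @param pixels Pixel positions.
#' @return Wavelengths in nm.
#' @export
pixels_to_nm <- function(calib, pixels) {
  stopifnot(inherits(calib, "wavelength_calibration"))
  calib$intercept + calib$slope * pixels
}

#' Emulate band-averaged values from a continuous spectrum
#'
#' Responsivity-weighted mean of the spectrum over each band:
#' `value_b = sum(spectrum * resp_b) / sum(resp_b)`.  This is how a
#' camera band "sees" a continuous property spectrum, and how
#' spectroscopy (SFDS) data are collapsed onto the imaging bands for
#' comparison.
#'
#' @param spectrum A `spectrum_curve` covering every band's support.
#' @param bands List of `band_responsivity`.
#' @return Named numeric vector, one value per band.
#' @export
emulate_band_values <- function(spectrum, bands) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  vapply(bands, function(b) {
    w <- b$curve$wavelengths
    # effective support: responsivity above 1e-6 of the band peak
    # (Gaussian-shaped bands never reach exactly zero)
    sup <- w[b$curve$values > 1e-6 * max(b$curve$values)]
    if (length(sup) &&
        (min(sup) < min(spectrum$wavelengths) ||
         max(sup) > max(spectrum$wavelengths))) {
      stop("spectrum does not cover the support of band ", b$name)
    }
    sv <- approx(spectrum$wavelengths, spectrum$values, xout = w,
                 rule = 2)$y
    sum(sv * b$curve$values) / sum(b$curve$values)
  }, numeric(1))
}
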