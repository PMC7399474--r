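#' Specification of one projected sinusoidal pattern
#'
#' @param fx Spatial frequency at the sample plane (mm^-1), >= 0.
#' @param phase Phase in degrees; one of 0, 120, 240.
#' @param width,height Pattern size in pixels.
#' @param pixel_pitch Projected pixel pitch at the sample plane (mm/px).
#' @param dc_level,ac_level DC and AC levels as fractions of full scale;
#'   `dc + ac <= 1` so the sinusoid never clips.  Defaults 0.5/0.5
#'   (full-contrast unclipped sinusoid).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(fx, phase, width, height, pixel_pitch,
                         dc_level = 0.5, ac_level = 0.5) {
  if (fx < 0) stop("fx must be >= 0")
  if (!phase %in% c(0, 120, 240)) stop("phase must be 0, 120 or 240 degrees")
  if (dc_level + ac_level > 1 + 1e-12) {
    stop("dc_level + ac_level must be <= 1 (pattern would clip)")
  }
  if (dc_level < ac_level) stop("dc_level < ac_level: pattern would go negative")
  if (fx * pixel_pitch >= 0.5) {
    stop("fx * pixel_pitch >= 0.5: pattern is beyond the projector Nyquist limit")
  }
  structure(list(fx = fx, phase = phase, width = as.integer(width),
                 height = as.integer(height), pixel_pitch = pixel_pitch,
                 dc_level = dc_level, ac_level = ac_level),
            class = "pattern_spec")
}

#' Generate a sinusoidal illumination pattern
#'
#' `P(x, y) = dc + ac cos(2 pi fx x pitch + phase)`, modulated along the
#' image x axis with the origin at the top-left pixel.  For `fx = 0` the
#' three phases give three distinct uniform fields at
#' `dc + ac cos(phase)`, so three-phase demodulation applies unchanged at
#' zero frequency.
#'
#' @param spec A [pattern_spec()].
#' @return Matrix (`height` x `width`) with values in `[0, 1]`.
#' @export
make_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  x <- (seq_len(spec$width) - 1) * spec$pixel_pitch
  row <- spec$dc_level + spec$ac_level *
    cos(2 * pi * spec$fx * x + spec$phase * pi / 180)
  matrix(rep(row, each = spec$height), nrow = spec$height)
}

#' Estimate a projector gamma curve from level/intensity measurements
#'
#' Commercial projectors apply an intentional nonlinear (gamma) mapping
#' from commanded 8-bit level to emitted intensity.  This fits a monotone
#' lookup curve to measured (level, intensity) pairs; non-monotone
#' measurements are regularized by isotonic regression (pool adjacent
#' violators) before storage.  Output intensities are normalized to the
#' maximum measurement.
#'
#' @param levels Commanded device levels (0-255), >= 8 distinct values
#'   spanning the range.
#' @param measured Observed relative intensities, >= 0.
#' @return A list of class `gamma_curve` with `input_levels` and
#'   `measured_output` (monotone, in `[0, 1]`).
#' @export
estimate_gamma <- function(levels, measured) {
  stopifnot(length(levels) == length(measured))
  if (length(unique(levels)) < 2) stop("need at least 2 distinct levels")
  if (length(unique(levels)) < 8) {
    warning("fewer than 8 distinct levels: gamma curve will be coarse")
  }
  if (any(measured < 0)) stop("measured intensities must be >= 0")
  o <- order(levels)
  levels <- levels[o]; measured <- measured[o]
  fit <- isoreg(levels, measured)
  out <- fit$yf / max(fit$yf)
  structure(list(input_levels = levels, measured_output = out),
            class = "gamma_curve")
}

#' An analytic power-law gamma curve
#'
#' Convenience constructor for `output = (level/255)^gamma` sampled on a
#' level grid; used by the synthetic projector and in tests.
#'
#' @param gamma Power-law exponent (> 0); 1 is the identity.
#' @param levels Sample levels (default 0:255).
#' @return A `gamma_curve`.
#' @export
power_gamma_curve <- function(gamma, levels = 0:255) {
  stopifnot(gamma > 0)
  structure(list(input_levels = levels,
                 measured_output = (levels / 255)^gamma),
            class = "gamma_curve")
}

#' Pre-compensate a pattern for projector gamma
#'
#' Applies the inverse of the measured gamma curve so that, after the
#' projector's internal gamma, the emitted intensity is linear in the
#' requested pattern.  The result is quantized to 8-bit device levels.
#' Requested intensities outside the measured output range are clipped
#' with a warning.
#'
#' @param pattern Matrix with values in `[0, 1]` (target relative
#'   intensity).
#' @param curve A [estimate_gamma()] / [power_gamma_curve()] result.
#' @return Integer matrix of device levels 0-255.
#' @export
pregamma <- function(pattern, curve) {
  stopifnot(inherits(curve, "gamma_curve"))
  out <- curve$measured_output / max(curve$measured_output)
  lo <- min(out); hi <- max(out)
  p <- pattern
  n_clip <- sum(p < lo | p > hi)
  if (n_clip > 0) {
    warning(sprintf("%d pixel(s) outside the measured output range; clipped",
                    n_clip))
    p[p < lo] <- lo
    p[p > hi] <- hi
  }
  # invert: for each requested output, the device level producing it
  keep <- !duplicated(out)
  lev <- approx(out[keep], curve$input_levels[keep], xout = as.vector(p),
                rule = 2)$y
  matrix(as.integer(round(pmin(pmax(lev, 0), 255))), nrow = nrow(pattern))
}

#' Apply a gamma curve as the projector device would
#'
#' Maps commanded device levels to emitted relative intensity by linear
#' interpolation of the gamma curve; the synthetic-projector half of the
#' [pregamma()] round trip.
#'
#' @param levels Matrix of device levels 0-255.
#' @param curve A `gamma_curve`.
#' @return Matrix of emitted intensities in `[0, 1]`.
#' @export
apply_gamma_device <- function(levels, curve) {
  stopifnot(inherits(curve, "gamma_curve"))
  out <- curve$measured_output / max(curve$measured_output)
  v <- approx(curve$input_levels, out, xout = as.vector(levels), rule = 2)$y
  matrix(v, nrow = nrow(levels))
}

#' Three co-registered frames at phases 0/120/240 degrees
#'
#' @param I1,I2,I3 Non-negative intensity matrices of identical shape
#'   (linear scale: any camera nonlinearity must be removed upstream).
#' @param fx Spatial frequency (mm^-1).
#' @param band Band name.
#' @return An object of class `phase_triplet`.
#' @export
phase_triplet <- function(I1, I2, I3, fx = NA_real_, band = NA_character_) {
  if (!all(dim(I1) == dim(I2)) || !all(dim(I1) == dim(I3))) {
    stop("the three frames must have identical shapes")
  }
  if (min(I1, I2, I3) < 0) stop("intensities must be >= 0")
  structure(list(I1 = I1, I2 = I2, I3 = I3, fx = fx, band = band),
            class = "phase_triplet")
}

#' Three-phase demodulation to AC amplitude
#'
#' Recovers the spatial AC modulation amplitude per pixel from three
#' frames phase-shifted by 120 degrees:
#' `MAC = (sqrt(2)/3) sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`.
#' The result is invariant to a common offset and to a global phase shift
#' of the three frames.  No smoothing or windowing is applied.
#'
#' @param triplet A [phase_triplet()].
#' @return A list of class `demodulated_map` with the `mac` matrix and the
#'   triplet's `fx` and `band`.
#' @export
demodulate <- function(triplet) {
  stopifnot(inherits(triplet, "phase_triplet"))
  d12 <- triplet$I1 - triplet$I2
  d23 <- triplet$I2 - triplet$I3
  d31 <- triplet$I3 - triplet$I1
  mac <- sqrt(2) / 3 * sqrt(d12^2 + d23^2 + d31^2)
  structure(list(mac = mac, fx = triplet$fx, band = triplet$band),
            class = "demodulated_map")
}

#' Calibration reference measured on a phantom of known optical properties
#'
#' Pairs the demodulated AC amplitude acquired on the reference phantom
#' with the phantom's theoretical diffuse reflectance from the forward
#' model.  The light-source intensity and the system transfer function
#' never appear: the MAC ratio in [calibrate()] cancels them by
#' construction.
#'
#' @param mac_ref List of `demodulated_map`s measured on the reference,
#'   keyed by `fx|band`.
#' @param rd_ref Named numeric vector of theoretical reflectance values in
#'   (0, 1), same `fx|band` keys.
#' @return An object of class `calibration_reference`.
#' @export
calibration_reference <- function(mac_ref, rd_ref) {
  stopifnot(is.list(mac_ref), is.numeric(rd_ref))
  if (!all(names(mac_ref) %in% names(rd_ref))) {
    stop("every reference MAC needs a matching theoretical Rd")
  }
  if (any(rd_ref <= 0 | rd_ref >= 1)) stop("rd_ref must be in (0, 1)")
  structure(list(mac_ref = mac_ref, rd_ref = rd_ref),
            class = "calibration_reference")
}

ref_key <- function(fx, band) sprintf("%s|%s", format(fx, digits = 10), band)

#' Calibrate a demodulated map to diffuse reflectance
#'
#' `Rd_tissue = (MAC / MAC_ref) * Rd_ref` per pixel, at the matching
#' spatial frequency and band.  The reference MAC is median-smoothed
#' (5x5) before division to suppress reference speckle (division noise
#' amplification); set `smooth_ref = FALSE` for strictly per-pixel
#' division.  Output is clipped to `[0, 1.5]`; clipped pixels are counted
#' in the `n_flagged` attribute.
#'
#' @param mac_tissue A `demodulated_map` from the sample.
#' @param ref A [calibration_reference()].
#' @param smooth_ref Median-smooth the reference MAC first (default TRUE).
#' @return Matrix of Rd values with attributes `fx`, `band`, `n_flagged`.
#' @export
calibrate <- function(mac_tissue, ref, smooth_ref = TRUE) {
  stopifnot(inherits(mac_tissue, "demodulated_map"),
            inherits(ref, "calibration_reference"))
  key <- ref_key(mac_tissue$fx, mac_tissue$band)
  if (!key %in% names(ref$mac_ref)) {
    stop("no reference acquisition for fx = ", mac_tissue$fx,
         ", band = ", mac_tissue$band)
  }
  mref <- ref$mac_ref[[key]]$mac
  if (smooth_ref) mref <- median_filter(mref, 5L)
  if (any(mref <= 0)) {
    stop("reference MAC is zero at some pixels; cannot calibrate")
  }
  rd <- mac_tissue$mac / mref * ref$rd_ref[[key]]
  n_flagged <- sum(rd < 0 | rd > 1.5)
  rd[rd > 1.5] <- 1.5
  rd[rd < 0] <- 0
  attr(rd, "fx") <- mac_tissue$fx
  attr(rd, "band") <- mac_tissue$band
  attr(rd, "n_flagged") <- n_flagged
  rd
}

#' Square median filter with edge replication
#'
#' @param x Numeric matrix.
#' @param size Odd window size (default 5).
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(x, size = 5L) {
  stopifnot(size %% 2L == 1L)
  h <- (size - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  xp <- x[ri, ci, drop = FALSE]
  stack <- array(NA_real_, dim = c(nr, nc, size * size))
  k <- 0L
  for (dr in 0:(size - 1L)) {
    for (dc in 0:(size - 1L)) {
      k <- k + 1L
      stack[, , k] <- xp[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  apply(stack, c(1, 2), median)
}
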