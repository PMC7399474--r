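# Band responsivity construction, band statistics, selection, wavelength
# calibration and band-averaged emulation.

test_that("cross_channel_product multiplies curves and validates grids", {
  grid <- default_wavelength_grid()
  led <- gaussian_curve(540, 15)
  flt <- gaussian_curve(470, 20)

  # product of two Gaussians peaks at the precision-weighted mean
  band <- cross_channel_product(led, flt, "GB")
  s <- band_stats(band)
  expect_equal(s$lambda0, (540 * 20^2 + 470 * 15^2) / (15^2 + 20^2),
               tolerance = 0.05)  # 514.8 nm

  # commutative and degree-1 homogeneous in each argument
  band_sw <- cross_channel_product(flt, led, "GB")
  expect_equal(band$curve$values, band_sw$curve$values)
  led2 <- spectrum_curve(grid, 3 * led$values)
  band2 <- cross_channel_product(led2, flt, "GB")
  expect_equal(band2$curve$values, 3 * band$curve$values)

  # identity filter returns the LED curve
  ones <- spectrum_curve(grid, rep(1, length(grid)))
  expect_equal(cross_channel_product(led, ones, "GG")$curve$values,
               led$values)

  expect_error(cross_channel_product(
    spectrum_curve(400:500, rep(1, 101)), flt, "GB"), "resample")
  expect_error(cross_channel_product(led, flt, "XY"), "band name")
})

test_that("disjoint LED/filter supports give a zero band with zero strength", {
  grid <- seq(380, 720, 1)
  led <- spectrum_curve(grid, ifelse(grid >= 600 & grid <= 650, 1, 0))
  flt <- spectrum_curve(grid, ifelse(grid >= 400 & grid <= 500, 1, 0))
  bands <- band_set(list(B = flt, G = led, R = led),
                    list(B = led, G = flt, R = flt))
  expect_true(all(bands$BB$curve$values == 0))
  expect_equal(bands$BB$relative_strength, 0)
})

test_that("band_stats: weighted center and half-maximum FWHM", {
  grid <- seq(380, 720, 1)
  # symmetric triangle centered at 550
  tri <- pmax(0, 1 - abs(grid - 550) / 40)
  b <- structure(list(name = "GG", curve = spectrum_curve(grid, tri),
                      relative_strength = 1), class = "band_responsivity")
  s <- band_stats(b)
  expect_equal(s$lambda0, 550, tolerance = 1e-9)
  expect_equal(s$fwhm, 40, tolerance = 0.01)  # half-max crossings at +/-20

  # Gaussian FWHM = 2 sqrt(2 ln 2) sigma = 23.548 for sigma 10
  g <- structure(list(name = "GG", curve = gaussian_curve(550, 10),
                      relative_strength = 1), class = "band_responsivity")
  expect_equal(band_stats(g)$fwhm, 2 * sqrt(2 * log(2)) * 10,
               tolerance = 1)

  # invariant under uniform rescaling
  g5 <- structure(list(name = "GG",
                       curve = spectrum_curve(grid,
                                              5 * g$curve$values),
                       relative_strength = 1), class = "band_responsivity")
  expect_equal(band_stats(g5)$lambda0, band_stats(g)$lambda0)
  expect_equal(band_stats(g5)$fwhm, band_stats(g)$fwhm)

  zero <- structure(list(name = "BR",
                         curve = spectrum_curve(grid, rep(0, length(grid))),
                         relative_strength = 0), class = "band_responsivity")
  expect_error(band_stats(zero), "unusable band")

  expect_match(format_band_stats(band_stats(g)), "^550 \\+/- 12 nm$")
})

test_that("lambda0 is stable under wavelength grid refinement", {
  coarse <- seq(380, 720, 2)
  fine <- seq(380, 720, 1)
  for (grid in list(coarse, fine)) {
    b <- structure(list(name = "GG", curve = gaussian_curve(533.3, 18, grid),
                        relative_strength = 1), class = "band_responsivity")
    if (identical(grid, coarse)) l_coarse <- band_stats(b)$lambda0
    else l_fine <- band_stats(b)$lambda0
  }
  expect_lt(abs(l_coarse - l_fine), 0.5)
})

test_that("select_bands keeps primaries, applies strength and blue rules", {
  bands <- default_band_set()
  expect_equal(select_bands(bands), c("BB", "GB", "GG", "GR", "RR"))

  # threshold 0 and no wavelength rule retains all nine
  expect_setequal(select_bands(bands, strength_threshold = 0,
                               min_lambda0 = -Inf),
                  c("BB", "BG", "BR", "GB", "GG", "GR", "RB", "RG", "RR"))

  # all cross-channels zeroed: only the primaries remain
  z <- bands
  for (nm in setdiff(names(z), c("BB", "GG", "RR"))) {
    z[[nm]]$curve$values[] <- 0
    z[[nm]]$relative_strength <- 0
  }
  expect_setequal(select_bands(z), c("BB", "GG", "RR"))

  # BG is moderately strong but rejected by the blue-absorption rule
  expect_gte(bands$BG$relative_strength, 0.05)
  expect_lt(band_stats(bands$BG)$lambda0, 500)
})

test_that("two-point wavelength calibration is exact and invertible", {
  cal <- wavelength_calibrate(c(100, 400), c(532, 650))
  expect_equal(pixels_to_nm(cal, 250), 591)
  expect_equal(pixels_to_nm(cal, c(100, 400)), c(532, 650))

  # round trip: a profile generated with known dispersion recovers it
  true_slope <- 0.39; true_int <- 493
  px <- c(100, 400)
  cal2 <- wavelength_calibrate(px, true_int + true_slope * px)
  expect_equal(cal2$slope, true_slope, tolerance = 1e-12)
  expect_equal(cal2$intercept, true_int, tolerance = 1e-9)

  expect_error(wavelength_calibrate(c(100, 100), c(532, 650)), "distinct")
})

test_that("emulate_band_values is a responsivity-weighted mean", {
  bands <- default_bands()
  grid <- default_wavelength_grid()

  flat <- spectrum_curve(grid, rep(0.37, length(grid)))
  expect_equal(unname(emulate_band_values(flat, bands)),
               rep(0.37, length(bands)), tolerance = 1e-12)
  zero <- spectrum_curve(grid, rep(0, length(grid)))
  expect_equal(unname(emulate_band_values(zero, bands)),
               rep(0, length(bands)))

  # s(lambda) = lambda returns each band's weighted center
  lin <- spectrum_curve(grid, grid)
  vals <- emulate_band_values(lin, bands)
  l0 <- vapply(bands, function(b) band_stats(b)$lambda0, numeric(1))
  expect_equal(unname(vals), unname(l0), tolerance = 1e-9)

  # linearity in the spectrum
  s1 <- spectrum_curve(grid, runif(length(grid)))
  s2 <- spectrum_curve(grid, runif(length(grid)))
  mix <- spectrum_curve(grid, 2 * s1$values + 3 * s2$values)
  expect_equal(emulate_band_values(mix, bands),
               2 * emulate_band_values(s1, bands) +
                 3 * emulate_band_values(s2, bands), tolerance = 1e-12)

  # a spectrum that stops short of a band's support is rejected by name
  short <- spectrum_curve(seq(600, 720, 1), rep(1, 121))
  expect_error(emulate_band_values(short, bands), "band BB")
})

test_that("spectrum CSV round trip preserves curves", {
  path <- withr::local_tempfile(fileext = ".csv")
  curve <- gaussian_curve(520, 25)
  write_spectrum_csv(curve, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$wavelengths, curve$wavelengths)
  expect_equal(back$values, curve$values)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:3, b = 4:6), bad, row.names = FALSE)
  expect_error(read_spectrum_csv(bad), "wavelength_nm")
})
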