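# Pattern generation, gamma compensation, three-phase demodulation and
# reference calibration.

test_that("make_pattern produces the requested sinusoid", {
  # fx = 0, phase 0: uniform field at dc + ac
  p0 <- make_pattern(pattern_spec(0, 0, 16, 8, 0.5))
  expect_true(all(p0 == 1.0))
  expect_equal(dim(p0), c(8L, 16L))
  # fx = 0 phases give three distinct flat levels
  lv <- sapply(c(0, 120, 240), function(ph) {
    make_pattern(pattern_spec(0, ph, 4, 4, 0.5))[1, 1]
  })
  expect_equal(lv, 0.5 + 0.5 * cos(c(0, 120, 240) * pi / 180))

  # fx = 0.05 mm^-1 at 0.1 mm/px: spatial period exactly 200 px
  p <- make_pattern(pattern_spec(0.05, 0, 400, 2, 0.1))
  expect_equal(p[1, 201], p[1, 1], tolerance = 1e-12)
  expect_equal(p[1, 1], 1.0)           # crest at x = 0
  expect_equal(p[1, 101], 0, tolerance = 1e-12)  # trough half a period in

  expect_error(pattern_spec(0, 0, 4, 4, 0.5, dc_level = 0.7, ac_level = 0.5),
               "clip")
  expect_error(pattern_spec(4, 0, 4, 4, 0.2), "Nyquist")
})

test_that("estimate_gamma fits a monotone curve and pregamma inverts it", {
  # proportional measurements give the identity curve
  lv <- seq(0, 255, length.out = 16)
  ident <- estimate_gamma(lv, lv / 255)
  expect_equal(ident$measured_output, lv / 255, tolerance = 1e-12)

  # known power-law generator recovered within 1% mid-range
  g22 <- estimate_gamma(lv, (lv / 255)^2.2)
  mids <- seq(64, 192, by = 8)
  interp <- approx(g22$input_levels, g22$measured_output, xout = mids)$y
  expect_lt(max(abs(interp - (mids / 255)^2.2)), 0.01)

  # noisy non-monotone measurements are isotonically regularized
  set.seed(1)
  noisy <- (lv / 255)^2.2 + rnorm(16, sd = 0.01)
  curve <- estimate_gamma(lv, pmax(noisy, 0))
  expect_true(all(diff(curve$measured_output) >= 0))

  expect_error(estimate_gamma(c(1, 1), c(0, 1)), "distinct")
})

test_that("pregamma followed by the gamma device is the identity", {
  pat <- matrix(seq(0, 1, length.out = 256), nrow = 16)

  ident <- power_gamma_curve(1)
  out_id <- apply_gamma_device(pregamma(pat, ident), ident)
  expect_lt(max(abs(out_id - pat)), 0.5 / 255 + 1e-9)

  # gamma 2.2: the device's output resolution near full scale is
  # gamma/255 per level, which bounds the round-trip error
  g <- power_gamma_curve(2.2)
  out <- apply_gamma_device(pregamma(pat, g), g)
  expect_lt(max(abs(out - pat)), 2.2 / 255)

  cpat <- matrix(0.42, 4, 4)
  expect_true(all(pregamma(cpat, g) == pregamma(cpat, g)[1, 1]))
})

test_that("demodulate implements the three-phase amplitude identity", {
  # constant frames demodulate to exactly zero
  cst <- phase_triplet(matrix(7, 4, 4), matrix(7, 4, 4), matrix(7, 4, 4))
  expect_true(all(demodulate(cst)$mac == 0))

  # analytic triplet returns the AC amplitude at every pixel
  tri <- analytic_triplet(100, 50, 0.3, 0.05)
  expect_equal(max(abs(demodulate(tri)$mac - 50)), 0, tolerance = 1e-10)

  # single pixel hand evaluation
  tri1 <- phase_triplet(matrix(10), matrix(20), matrix(30))
  expect_equal(demodulate(tri1)$mac[1, 1], sqrt(2) / 3 * sqrt(600),
               tolerance = 1e-12)
  expect_equal(demodulate(tri1)$mac[1, 1], 11.547, tolerance = 1e-4)

  # offset and common-phase invariance
  tri_off <- phase_triplet(tri$I1 + 13, tri$I2 + 13, tri$I3 + 13)
  expect_equal(demodulate(tri_off)$mac, demodulate(tri)$mac,
               tolerance = 1e-12)
  tri_ph <- analytic_triplet(100, 50, 0.3 + 1.1, 0.05)
  expect_equal(demodulate(tri_ph)$mac, demodulate(tri)$mac,
               tolerance = 1e-9)

  expect_error(phase_triplet(matrix(1, 2, 2), matrix(1, 2, 3),
                             matrix(1, 2, 2)), "shape")
})

test_that("demodulation agrees with a least-squares sinusoid-fit oracle", {
  set.seed(42)
  for (rep in 1:20) {
    a0 <- runif(1, 50, 150); a1 <- runif(1, 5, min(a0, 80))
    phi <- runif(1, 0, 2 * pi); fx <- runif(1, 0, 0.15)
    tri <- analytic_triplet(a0, a1, phi, fx, n_px = 8)
    mac <- demodulate(tri)$mac
    expect_equal(mac, ls_amplitude(tri$I1, tri$I2, tri$I3),
                 tolerance = 1e-9)
    expect_lt(max(abs(mac / a1 - 1)), 1e-10)
  }
})

test_that("demodulation recovers AC at fx = 0 and rectifies pure noise", {
  # uniform-field scheme: three flat frames carry the amplitude
  a0 <- 80; a1 <- 30
  frames <- lapply(c(0, 120, 240) * pi / 180, function(ph) {
    matrix(a0 + a1 * cos(ph), 4, 4)
  })
  tri <- phase_triplet(frames[[1]], frames[[2]], frames[[3]], fx = 0)
  expect_equal(demodulate(tri)$mac[1, 1], a1, tolerance = 1e-12)

  # pure noise has positive expected MAC (rectified noise floor)
  set.seed(7)
  noise <- phase_triplet(matrix(abs(rnorm(400, 50, 2)), 20),
                         matrix(abs(rnorm(400, 50, 2)), 20),
                         matrix(abs(rnorm(400, 50, 2)), 20))
  expect_gt(mean(demodulate(noise)$mac), 0)
})

test_that("calibrate applies the reference ratio with linearity", {
  mac <- matrix(0.2, 8, 8)
  ref_map <- structure(list(mac = matrix(0.4, 8, 8), fx = 0.05, band = "GG"),
                       class = "demodulated_map")
  ref <- calibration_reference(
    setNames(list(ref_map), rgbsfdi:::ref_key(0.05, "GG")),
    setNames(0.6, rgbsfdi:::ref_key(0.05, "GG")))
  tis <- structure(list(mac = mac, fx = 0.05, band = "GG"),
                   class = "demodulated_map")

  rd <- calibrate(tis, ref)
  expect_true(all(rd == 0.3))  # 0.2 / 0.4 * 0.6

  # self-calibration returns rd_ref identically
  self <- structure(list(mac = matrix(0.4, 8, 8), fx = 0.05, band = "GG"),
                    class = "demodulated_map")
  expect_true(all(calibrate(self, ref, smooth_ref = FALSE) == 0.6))
  expect_true(all(calibrate(self, ref) == 0.6))

  # linear in MAC
  tis2 <- structure(list(mac = 2 * mac, fx = 0.05, band = "GG"),
                    class = "demodulated_map")
  expect_equal(calibrate(tis2, ref), 2 * calibrate(tis, ref),
               ignore_attr = TRUE)

  miss <- structure(list(mac = mac, fx = 0.1, band = "GG"),
                    class = "demodulated_map")
  expect_error(calibrate(miss, ref), "no reference")

  # out-of-range pixels are clipped and counted
  hot <- structure(list(mac = matrix(10, 8, 8), fx = 0.05, band = "GG"),
                   class = "demodulated_map")
  out <- calibrate(hot, ref)
  expect_true(all(out == 1.5))
  expect_equal(attr(out, "n_flagged"), 64)
})

test_that("self-calibration through the speckled-reference path is exact per pixel", {
  set.seed(3)
  speckle <- matrix(runif(64, 0.3, 0.5), 8, 8)
  ref_map <- structure(list(mac = speckle, fx = 0, band = "RR"),
                       class = "demodulated_map")
  key <- rgbsfdi:::ref_key(0, "RR")
  ref <- calibration_reference(setNames(list(ref_map), key),
                               setNames(0.55, key))
  tis <- structure(list(mac = speckle, fx = 0, band = "RR"),
                   class = "demodulated_map")
  expect_true(all(calibrate(tis, ref, smooth_ref = FALSE) == 0.55))
})

test_that("median_filter preserves constants and removes salt noise", {
  m <- matrix(2, 9, 9)
  expect_equal(median_filter(m), m)
  m[5, 5] <- 100
  expect_equal(median_filter(m)[5, 5], 2)
})
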