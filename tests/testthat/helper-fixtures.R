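# Shared fixtures, built once per test run and cached.  Table photon
# counts are scaled down from the 1e6 production default to keep the suite
# inside its time budget; the accuracy-critical Monte Carlo comparisons in
# test-acceptance.R use full 1e6-photon runs.

.fixtures <- new.env(parent = emptyenv())

# medium-fidelity table used by pipeline/validation/acceptance tests
shared_table <- function() {
  if (is.null(.fixtures$table)) {
    .fixtures$table <- build_table(
      mu_a_grid = exp(seq(log(0.005), log(0.5), length.out = 12)),
      mu_s_prime_grid = exp(seq(log(0.3), log(5), length.out = 8)),
      fx_grid = c(0, 0.0333, 0.05, 0.1, 0.15, 0.2),
      g = 0.8, n = 1.4, n_photons = 1e5, seed = 4242)
  }
  .fixtures$table
}

# small fast table for inversion unit tests (self-consistency only)
small_table <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- build_table(
      mu_a_grid = exp(seq(log(0.005), log(0.5), length.out = 10)),
      mu_s_prime_grid = exp(seq(log(0.3), log(5), length.out = 7)),
      fx_grid = c(0, 0.0333, 0.05, 0.1),
      g = 0.8, n = 1.4, n_photons = 1e4, seed = 77)
  }
  .fixtures$small
}

# analytic three-phase triplet at one pixel row
analytic_triplet <- function(a0, a1, phi0, fx, n_px = 32, pitch = 0.5) {
  x <- (seq_len(n_px) - 1) * pitch
  frames <- lapply(c(0, 120, 240) * pi / 180, function(ph) {
    matrix(a0 + a1 * cos(2 * pi * fx * x + phi0 + ph), nrow = 1)
  })
  phase_triplet(frames[[1]], frames[[2]], frames[[3]], fx = fx, band = "GG")
}

# independent amplitude oracle: least-squares sinusoid fit in the phase
# dimension (I_i = a0 + a1 cos(delta_i + phi) for deltas 0/120/240)
ls_amplitude <- function(i1, i2, i3) {
  delta <- c(0, 120, 240) * pi / 180
  X <- cbind(1, cos(delta), sin(delta))
  amp <- matrix(NA_real_, nrow = nrow(i1), ncol = ncol(i1))
  for (r in seq_len(nrow(i1))) {
    for (c in seq_len(ncol(i1))) {
      beta <- solve(crossprod(X), crossprod(X, c(i1[r, c], i2[r, c], i3[r, c])))
      amp[r, c] <- sqrt(beta[2]^2 + beta[3]^2)
    }
  }
  amp
}

# synthetic exit-record object for hand-evaluated absorption tests
fake_records <- function(radius, path, weight = rep(1, length(radius)),
                         n_launched = length(radius)) {
  structure(list(exit_radius = radius, path_length = path, weight = weight,
                 n_launched = n_launched, n_terminated = 0L),
            class = "photon_exit_records")
}

gaussian_curve <- function(mu, sigma, grid = default_wavelength_grid()) {
  spectrum_curve(grid, exp(-(grid - mu)^2 / (2 * sigma^2)))
}
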