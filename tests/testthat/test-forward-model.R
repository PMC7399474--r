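# White Monte Carlo, absorption weighting, Hankel transform, diffusion
# oracle, reflectance table.

test_that("run_white_mc validates inputs and is seed-deterministic", {
  expect_error(run_white_mc(-1, seed = 1), "mu_s_prime")
  expect_error(run_white_mc(1, n = 0.9, seed = 1), "n must be")
  expect_error(run_white_mc(1), "seed")

  a <- run_white_mc(1.0, g = 0.8, n = 1.4, n_photons = 2000, seed = 11)
  b <- run_white_mc(1.0, g = 0.8, n = 1.4, n_photons = 2000, seed = 11)
  expect_identical(a, b)
  c <- run_white_mc(1.0, g = 0.8, n = 1.4, n_photons = 2000, seed = 12)
  expect_false(identical(a$exit_radius, c$exit_radius))
})

test_that("matched-boundary non-absorbing half-space returns almost all photons", {
  rec <- run_white_mc(1.0, g = 0, n = 1, n_photons = 2e4, seed = 3,
                      max_path = 4000)
  expect_gte(length(rec$exit_radius) / rec$n_launched, 0.9)
  # a photon's path is at least the chord to its exit point
  expect_true(all(rec$path_length >= rec$exit_radius - 1e-9))
  expect_true(all(rec$weight > 0 & rec$weight <= 1))
})

test_that("similarity relation: g = 0.8 and g = 0 runs agree on mean exit radius", {
  hg <- run_white_mc(1.0, g = 0.8, n = 1.4, n_photons = 3e4, seed = 21)
  iso <- run_white_mc(1.0, g = 0, n = 1.4, n_photons = 3e4, seed = 22)
  expect_lt(abs(mean(hg$exit_radius) / mean(iso$exit_radius) - 1), 0.1)
})

test_that("apply_absorption implements Beer-Lambert pathlength weighting", {
  rec <- run_white_mc(1.5, g = 0.8, n = 1.4, n_photons = 5000, seed = 5)
  edges <- seq(0, 51.2, by = 0.1)

  r0 <- apply_absorption(rec, 0, edges)
  total <- sum(r0$rd_per_area * pi * diff(edges^2))
  in_range <- rec$exit_radius <= max(edges)
  expect_equal(total, sum(rec$weight[in_range]) / rec$n_launched,
               tolerance = 1e-12)

  r1 <- apply_absorption(rec, 0.05, edges)
  r2 <- apply_absorption(rec, 0.10, edges)
  nz <- r1$rd_per_area > 0
  expect_true(all(r2$rd_per_area[nz] < r1$rd_per_area[nz]))

  # single hand-evaluated record: weight 1, L = 10 mm, mu_a = 0.1
  single <- apply_absorption(fake_records(5, 10), 0.1, edges)
  expect_equal(sum(single$rd_per_area * pi * diff(edges^2)), exp(-1),
               tolerance = 1e-12)

  expect_error(apply_absorption(fake_records(numeric(0), numeric(0)), 0.1),
               "run the Monte Carlo")
  expect_error(apply_absorption(rec, -0.1), "mu_a")
})

test_that("hankel_to_fx is exact at fx = 0 and matches the Gaussian pair", {
  edges <- seq(0, 30, by = 0.05)
  r <- (edges[-1] + edges[-length(edges)]) / 2
  sigma <- 3
  rad <- structure(list(bin_edges = edges,
                        rd_per_area = exp(-r^2 / (2 * sigma^2)),
                        n_photons_launched = 1L),
                   class = "radial_reflectance")
  total <- sum(rad$rd_per_area * pi * diff(edges^2))
  expect_equal(hankel_to_fx(rad, 0), total, tolerance = 1e-14)

  # closed form: 2 pi sigma^2 exp(-2 pi^2 sigma^2 fx^2)
  fx <- c(0.05, 0.1, 0.15, 0.2)
  expect_equal(hankel_to_fx(rad, fx),
               2 * pi * sigma^2 * exp(-2 * pi^2 * sigma^2 * fx^2),
               tolerance = 0.01)

  # oscillatory cancellation at high fx
  expect_lt(abs(hankel_to_fx(rad, 5)), 0.05 * hankel_to_fx(rad, 0))
  expect_error(hankel_to_fx(rad, -0.1), "fx")
})

test_that("diffusion_rd matches its frozen formula evaluation and limits", {
  # frozen regression value, hand-evaluated through the formula chain
  p <- optical_properties(0.05, 1.5, g = 0.8, n = 1.4)
  expect_equal(diffusion_rd(p, 0.1), 0.3039239239, tolerance = 1e-9)

  # pure absorber limit: a' -> 0 drives Rd -> 0
  expect_lt(diffusion_rd(optical_properties(10, 0.001), 0), 1e-3)

  # strictly decreasing in fx
  rd <- diffusion_rd(p, seq(0, 0.3, by = 0.05))
  expect_true(all(diff(rd) < 0))

  # mu_a = 0, fx = 0 returns the finite a' = 1 limit, not an error
  expect_equal(diffusion_rd(optical_properties(0, 1.5), 0), 1)
  expect_true(all(rd >= 0 & rd <= 1))
})

test_that("build_table satisfies its invariants and is reproducible", {
  tab <- small_table()
  expect_true(all(tab$rd >= 0 & tab$rd <= 1))
  # monotone decreasing along mu_a on every line
  for (j in seq_along(tab$mu_s_prime_grid)) {
    for (k in seq_along(tab$fx_grid)) {
      expect_true(all(diff(tab$rd[, j, k]) < 0))
    }
  }
  # non-increasing along fx (<= 0.3 mm^-1 covers the whole grid)
  for (i in seq_along(tab$mu_a_grid)) {
    for (j in seq_along(tab$mu_s_prime_grid)) {
      expect_true(all(diff(tab$rd[i, j, ]) <= 1e-12))
    }
  }
  rebuilt <- build_table(tab$mu_a_grid, tab$mu_s_prime_grid, tab$fx_grid,
                         g = 0.8, n = 1.4, n_photons = 1e4, seed = 77)
  expect_identical(rebuilt$rd, tab$rd)
})

test_that("reflectance table serializes losslessly", {
  tab <- small_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_reflectance_table(tab, path)
  back <- read_reflectance_table(path)
  expect_equal(back$rd, tab$rd, tolerance = 1e-15)
  expect_equal(back$mu_a_grid, tab$mu_a_grid)
  expect_equal(back$metadata$seed, tab$metadata$seed)

  slice <- withr::local_tempfile(fileext = ".csv")
  export_fx_slice(tab, 0.05, slice)
  d <- read.csv(slice)
  expect_equal(nrow(d), length(tab$mu_a_grid) * length(tab$mu_s_prime_grid))
})

test_that("lookup_rd interpolates exactly at nodes and brackets between them", {
  tab <- small_table()
  g <- tab$metadata$g; n <- tab$metadata$n
  p_node <- optical_properties(tab$mu_a_grid[4], tab$mu_s_prime_grid[3],
                               g = g, n = n)
  expect_equal(lookup_rd(tab, p_node, tab$fx_grid), tab$rd[4, 3, ],
               tolerance = 1e-14)

  mid_a <- sqrt(tab$mu_a_grid[4] * tab$mu_a_grid[5])
  p_mid <- optical_properties(mid_a, tab$mu_s_prime_grid[3], g = g, n = n)
  v <- lookup_rd(tab, p_mid, 0.05)
  k <- which(tab$fx_grid == 0.05)
  expect_gte(v, min(tab$rd[4:5, 3, k]))
  expect_lte(v, max(tab$rd[4:5, 3, k]))

  expect_error(lookup_rd(tab, optical_properties(1.0, 1.5), 0), "mu_a")
  expect_error(lookup_rd(tab, optical_properties(0.1, 10), 0), "mu_s_prime")
  expect_error(lookup_rd(tab, optical_properties(0.1, 1.5), 0.123),
               "not tabulated")
})

test_that("interpolated lookup agrees with a direct simulation off-grid", {
  tab <- shared_table()
  g <- tab$metadata$g; n <- tab$metadata$n
  mu_a <- 0.04; mu_sp <- 1.1  # off-grid in both axes
  p <- optical_properties(mu_a, mu_sp, g = g, n = n)
  interp <- lookup_rd(tab, p, c(0, 0.05, 0.1))
  rec <- run_white_mc(mu_sp, g = g, n = n, n_photons = 1e5, seed = 999)
  direct <- hankel_to_fx(apply_absorption(rec, mu_a), c(0, 0.05, 0.1))
  expect_lt(max(abs(interp / direct - 1)), 0.03)
})

test_that("table agrees with the diffusion oracle in the diffusive regime", {
  # the closed form is only trustworthy while the modulation frequency is
  # small against the transport coefficient; beyond fx ~ 0.13 mu_s' the
  # approximation itself drifts past 10% regardless of MC fidelity
  tab <- shared_table()
  for (j in which(tab$mu_s_prime_grid >= 1)) {
    musp <- tab$mu_s_prime_grid[j]
    sel <- tab$fx_grid <= pmin(0.2, 0.13 * musp)
    for (i in which(tab$mu_a_grid <= musp / 50)) {
      p <- optical_properties(tab$mu_a_grid[i], musp, g = 0.8, n = 1.4)
      mc <- tab$rd[i, j, sel]
      di <- diffusion_rd(p, tab$fx_grid[sel])
      expect_lt(max(abs(mc / di - 1)), 0.10)
    }
  }
})
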