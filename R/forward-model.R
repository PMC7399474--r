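#' Run a white Monte Carlo photon transport simulation
#'
#' Simulates photon random walks in a homogeneous semi-infinite medium with
#' scattering only ("white" Monte Carlo: absorption is applied afterwards by
#' Beer-Lambert weighting of the recorded pathlengths, see
#' [apply_absorption()]).  Photons enter at the origin as a pencil beam;
#' specular entry is excluded (cross-polarized detection).  The top boundary
#' applies unpolarized Fresnel reflection; escape is sampled
#' probabilistically so every exit record carries weight 1.
#'
#' @param mu_s_prime Reduced scattering coefficient (mm^-1), > 0.  The
#'   simulation runs at `mu_s = mu_s_prime / (1 - g)`.
#' @param g Henyey-Greenstein anisotropy in `[0, 1)`.  `g = 0` with
#'   `mu_s = mu_s_prime` is the similarity-relation fast mode.
#' @param n Internal refractive index (>= 1).
#' @param n_photons Number of photons to launch.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param max_path Pathlength truncation (mm); photons exceeding it are
#'   terminated unrecorded.
#' @return A list of class `photon_exit_records` with numeric vectors
#'   `exit_radius` (mm), `path_length` (mm), `weight`, plus `n_launched`
#'   and `n_terminated` counts.
#' @examples
#' rec <- run_white_mc(1.0, g = 0, n = 1, n_photons = 1000, seed = 1)
#' length(rec$exit_radius) / rec$n_launched  # escape fraction near 1
#' @export
run_white_mc <- function(mu_s_prime, g = 0.8, n = 1.4, n_photons = 1e6,
                         seed, max_path = 4000) {
  if (!is.numeric(mu_s_prime) || mu_s_prime <= 0) {
    stop("mu_s_prime must be > 0")
  }
  if (n < 1) stop("n must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  mu_s <- mu_s_prime / (1 - g)
  out <- cpp_white_mc(mu_s, g, n, as.integer(n_photons), as.double(seed),
                      max_path)
  stopifnot(all(out$path_length >= out$exit_radius - 1e-9))
  class(out) <- "photon_exit_records"
  out
}

#' @export
print.photon_exit_records <- function(x, ...) {
  cat(sprintf("photon_exit_records: %d launched, %d exited, %d truncated\n",
              x$n_launched, length(x$exit_radius), x$n_terminated))
  invisible(x)
}

#' Apply absorption to white Monte Carlo exit records
#'
#' Scales each photon's weight by the Beer-Lambert factor
#' `exp(-mu_a * path_length)` and bins the result into annular rings,
#' normalized per launched photon and per annulus area.
#'
#' @param records Output of [run_white_mc()].
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param bin_edges Ascending radial bin edges (mm), starting at 0.
#'   Default: 512 annuli of 0.1 mm.
#' @return A list of class `radial_reflectance` with `bin_edges`,
#'   `rd_per_area` (mm^-2) and `n_photons_launched`.
#' @export
apply_absorption <- function(records, mu_a,
                             bin_edges = seq(0, 51.2, by = 0.1)) {
  if (!inherits(records, "photon_exit_records") ||
      length(records$exit_radius) == 0) {
    stop("no photon exit records: run the Monte Carlo first")
  }
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly ascending")
  }
  w <- records$weight * exp(-mu_a * records$path_length)
  idx <- findInterval(records$exit_radius, bin_edges,
                      rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  keep <- idx >= 1L & idx <= nb  # photons beyond the last edge are dropped
  sums <- numeric(nb)
  t <- tapply(w[keep], factor(idx[keep], levels = seq_len(nb)), sum)
  sums[!is.na(t)] <- t[!is.na(t)]
  area <- pi * diff(bin_edges^2)  # exact annulus areas
  structure(list(bin_edges = bin_edges,
                 rd_per_area = sums / (records$n_launched * area),
                 n_photons_launched = records$n_launched),
            class = "radial_reflectance")
}

#' Hankel-transform radial reflectance to the spatial frequency domain
#'
#' Computes `Rd(fx) = 2 pi * sum_i rd(r_i) J0(2 pi fx r_i) r_i dr_i` over
#' annular bins using bin-center radii (the zeroth-order Hankel transform
#' of the spatially resolved diffuse reflectance).  At `fx = 0` this equals
#' the radially integrated total reflectance to machine precision.
#'
#' @param radial A `radial_reflectance` from [apply_absorption()].
#' @param fx_list Spatial frequencies (mm^-1), >= 0.
#' @return Numeric vector of Rd values, one per `fx`.
#' @export
hankel_to_fx <- function(radial, fx_list) {
  stopifnot(inherits(radial, "radial_reflectance"))
  if (any(fx_list < 0)) stop("fx must be >= 0")
  e <- radial$bin_edges
  r <- (e[-1] + e[-length(e)]) / 2
  dr <- diff(e)
  vapply(fx_list, function(fx) {
    2 * pi * sum(radial$rd_per_area * besselJ(2 * pi * fx * r, 0) * r * dr)
  }, numeric(1))
}

#' Diffuse reflectance from the spatial-frequency diffusion approximation
#'
#' Closed-form standard diffusion approximation of spatially modulated
#' diffuse reflectance; used as an independent oracle for the Monte Carlo
#' forward model.  With `mutr = mu_a + mu_s'`, `a' = mu_s'/mutr`,
#' `mueff = sqrt(3 mu_a mutr)` and `mueff' = sqrt(mueff^2 + (2 pi fx)^2)`:
#' `Rd = 3 A a' / ((mueff'/mutr + 1) (mueff'/mutr + 3 A))`, where `A` is
#' the internal-reflection parameter derived from the refractive index
#' through the effective reflection coefficient
#' `Reff = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2`.
#' Valid in the diffusive regime (`mu_s'/mu_a` of order 10 or more).
#'
#' @param props An [optical_properties()] object.
#' @param fx Spatial frequency (mm^-1); vectorized.
#' @return Rd values in `[0, 1]`.
#' @export
diffusion_rd <- function(props, fx) {
  stopifnot(inherits(props, "optical_properties"))
  n <- props$n
  Reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - Reff) / (2 * (1 + Reff))
  mutr <- props$mu_a + props$mu_s_prime
  ap <- props$mu_s_prime / mutr
  mueff2 <- 3 * props$mu_a * mutr
  mueffp <- sqrt(mueff2 + (2 * pi * fx)^2)
  q <- mueffp / mutr
  3 * A * ap / ((q + 1) * (q + 3 * A))
}

#' Build a tabulated reflectance forward model
#'
#' Runs one white Monte Carlo per reduced-scattering grid value, applies
#' absorption per `mu_a` grid value and Hankel-transforms to each spatial
#' frequency, producing the lookup table the inverse solver interpolates.
#'
#' @param mu_a_grid Ascending absorption grid (mm^-1), > 0 (log
#'   interpolation).
#' @param mu_s_prime_grid Ascending reduced scattering grid (mm^-1).
#' @param fx_grid Ascending spatial frequencies (mm^-1) from 0.
#' @param g,n Medium constants shared by the whole table.
#' @param n_photons Photons per `mu_s'` value (default 1e6).
#' @param seed Mandatory integer seed; run `i` uses `seed + i - 1`.
#' @param max_path Pathlength truncation (mm).
#' @param bin_edges Radial binning passed to [apply_absorption()].
#' @return A `reflectance_table`: grids plus an `rd` array with dimensions
#'   `(mu_a, mu_s', fx)` and a metadata list.
#' @export
build_table <- function(mu_a_grid, mu_s_prime_grid, fx_grid,
                        g = 0.8, n = 1.4, n_photons = 1e6, seed,
                        max_path = 4000,
                        bin_edges = seq(0, 51.2, by = 0.1)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(!is.unsorted(mu_a_grid, strictly = TRUE),
            !is.unsorted(mu_s_prime_grid, strictly = TRUE),
            !is.unsorted(fx_grid, strictly = TRUE),
            all(mu_a_grid > 0), fx_grid[1] >= 0)
  rd <- array(NA_real_, dim = c(length(mu_a_grid), length(mu_s_prime_grid),
                                length(fx_grid)))
  for (j in seq_along(mu_s_prime_grid)) {
    rec <- run_white_mc(mu_s_prime_grid[j], g = g, n = n,
                        n_photons = n_photons, seed = seed + j - 1,
                        max_path = max_path)
    for (i in seq_along(mu_a_grid)) {
      radial <- apply_absorption(rec, mu_a_grid[i], bin_edges)
      rd[i, j, ] <- hankel_to_fx(radial, fx_grid)
    }
  }
  rd[rd < 0] <- 0  # Hankel ringing can undershoot by MC noise at high fx
  rd[rd > 1] <- 1
  structure(list(mu_a_grid = mu_a_grid, mu_s_prime_grid = mu_s_prime_grid,
                 fx_grid = fx_grid, rd = rd,
                 metadata = list(g = g, n = n, n_photons = n_photons,
                                 seed = seed, max_path = max_path)),
            class = "reflectance_table")
}

#' @export
print.reflectance_table <- function(x, ...) {
  cat(sprintf(paste0(
    "reflectance_table: %d mu_a x %d mu_s' x %d fx ",
    "(g = %g, n = %g, %g photons, seed %d)\n"),
    length(x$mu_a_grid), length(x$mu_s_prime_grid), length(x$fx_grid),
    x$metadata$g, x$metadata$n, x$metadata$n_photons, x$metadata$seed))
  invisible(x)
}

#' Interpolated reflectance lookup
#'
#' Bilinear interpolation in `(log mu_a, log mu_s')` at each tabulated
#' spatial frequency; exact at grid nodes.  Queries outside the grid or at
#' untabulated `fx` raise errors naming the offending axis.
#'
#' @param table A [build_table()] result.
#' @param props An [optical_properties()] object.
#' @param fx_list Frequencies to evaluate; each must match a tabulated fx.
#' @return Numeric Rd values, one per fx.
#' @export
lookup_rd <- function(table, props, fx_list) {
  stopifnot(inherits(table, "reflectance_table"),
            inherits(props, "optical_properties"))
  ag <- table$mu_a_grid; sg <- table$mu_s_prime_grid
  if (props$mu_a < ag[1] || props$mu_a > ag[length(ag)]) {
    stop(sprintf("mu_a = %g outside table range [%g, %g]",
                 props$mu_a, ag[1], ag[length(ag)]))
  }
  if (props$mu_s_prime < sg[1] || props$mu_s_prime > sg[length(sg)]) {
    stop(sprintf("mu_s_prime = %g outside table range [%g, %g]",
                 props$mu_s_prime, sg[1], sg[length(sg)]))
  }
  kf <- match_fx(table$fx_grid, fx_list)
  la <- log(ag); ls <- log(sg)
  i <- max(findInterval(log(props$mu_a), la), 1L)
  i <- min(i, length(la) - 1L)
  j <- max(findInterval(log(props$mu_s_prime), ls), 1L)
  j <- min(j, length(ls) - 1L)
  tx <- (log(props$mu_a) - la[i]) / (la[i + 1] - la[i])
  ty <- (log(props$mu_s_prime) - ls[j]) / (ls[j + 1] - ls[j])
  vapply(kf, function(k) {
    (1 - tx) * (1 - ty) * table$rd[i, j, k] +
      tx * (1 - ty) * table$rd[i + 1, j, k] +
      (1 - tx) * ty * table$rd[i, j + 1, k] +
      tx * ty * table$rd[i + 1, j + 1, k]
  }, numeric(1))
}

match_fx <- function(fx_grid, fx_list, tol = 1e-9) {
  vapply(fx_list, function(fx) {
    k <- which(abs(fx_grid - fx) < tol)
    if (length(k) != 1L) {
      stop(sprintf("fx = %g is not tabulated (fx axis: %s)", fx,
                   paste(signif(fx_grid, 4), collapse = ", ")))
    }
    k
  }, integer(1))
}

#' Serialize / restore a reflectance table
#'
#' Single-file JSON container with explicit grids, the flattened Rd array
#' and the run metadata (g, n, photon count, seed).
#'
#' @param table A `reflectance_table`.
#' @param path Output file path.
#' @return `read_reflectance_table()` returns the restored table;
#'   `write_reflectance_table()` returns `path` invisibly.
#' @export
write_reflectance_table <- function(table, path) {
  stopifnot(inherits(table, "reflectance_table"))
  obj <- list(format = "rgbsfdi-reflectance-table-v1",
              mu_a_grid = table$mu_a_grid,
              mu_s_prime_grid = table$mu_s_prime_grid,
              fx_grid = table$fx_grid,
              rd = as.vector(table$rd),
              metadata = table$metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reflectance_table
#' @export
read_reflectance_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rgbsfdi-reflectance-table-v1")) {
    stop("not a reflectance table file: ", path)
  }
  structure(list(mu_a_grid = obj$mu_a_grid,
                 mu_s_prime_grid = obj$mu_s_prime_grid,
                 fx_grid = obj$fx_grid,
                 rd = array(obj$rd, dim = c(length(obj$mu_a_grid),
                                            length(obj$mu_s_prime_grid),
                                            length(obj$fx_grid))),
                 metadata = as.list(obj$metadata)),
            class = "reflectance_table")
}

#' Export one fx-slice of a reflectance table as CSV
#'
#' @param table A `reflectance_table`.
#' @param fx The tabulated frequency to export.
#' @param path Output CSV path.
#' @export
export_fx_slice <- function(table, fx, path) {
  k <- match_fx(table$fx_grid, fx)
  d <- expand.grid(mu_a = table$mu_a_grid, mu_s_prime = table$mu_s_prime_grid)
  d$rd <- as.vector(table$rd[, , k])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
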