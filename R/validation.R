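# Phantom validation study: FOV-averaged SFDI estimates vs band-emulated
# spectroscopic (SFDS-like) ground truth, with linear regression stats.

#' Linear regression statistics for method comparison
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination, plus an RMSE agreement metric.  By default the RMSE is
#' computed about the identity line `y = x` (agreement between two
#' methods measuring the same quantity); `rmse_about = "fit"` uses the
#' regression residuals instead.
#'
#' @param x,y Paired measurements (same property, two methods).
#' @param rmse_about `"identity"` (default) or `"fit"`.
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `n`.
#' @export
regression_stats <- function(x, y, rmse_about = c("identity", "fit")) {
  rmse_about <- match.arg(rmse_about)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (diff(range(x)) == 0) stop("x is constant; regression is degenerate")
  fit <- lm(y ~ x)
  res <- if (rmse_about == "identity") y - x else stats::residuals(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 # exact agreement is a legitimate input here; silence
                 # summary.lm's "essentially perfect fit" warning
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 rmse = sqrt(mean(res^2)),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "regression_result: slope %.4f, intercept %.4g, R^2 = %.4f, RMSE = %.4g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Run the 16-phantom validation study end to end
#'
#' Simulates the full phantom grid plus a reference acquisition with the
#' synthetic instrument, runs the complete SFDI pipeline (demodulate,
#' calibrate, per-pixel fit, FOV average), and compares against
#' band-emulated ground truth from the idealized spectroscopic (SFDS)
#' counterpart of each phantom.  Both arms are processed at the shared
#' frequency subset `fx_fit` (default 0, 0.05, 0.1 mm^-1).
#'
#' @param table A reflectance table tabulating all of `fx_acquire` and
#'   `fx_fit`.
#' @param seed Integer seed driving all simulated noise.
#' @param noise_sigma Camera noise in 8-bit counts.
#' @param fx_acquire Frequencies projected during acquisition.
#' @param fx_fit Frequency subset used for fitting (>= 2).
#' @param instrument An [instrument_model()]; its `noise_sigma` is
#'   overridden by the `noise_sigma` argument.
#' @param ref_spec Reference phantom ([phantom_spec()]).
#' @param dir Scratch directory for simulated frames.
#' @param lambda_step Wavelength step (nm) of the SFDS ground-truth arm.
#' @param format Frame file format (`"bmp"`, `"png"`, or `"tiff"` for the
#'   quantization-free float mode).
#' @return A list of class `phantom_study`: `comparison` (data frame with
#'   one row per phantom x band x property), `regression` (list with
#'   `mu_a` and `mu_s_prime` [regression_stats()] results) and the study
#'   settings.
#' @export
run_phantom_study <- function(table, seed, noise_sigma = 1,
                              fx_acquire = c(0, 0.0333, 0.05, 0.1),
                              fx_fit = c(0, 0.05, 0.1),
                              instrument = instrument_model(),
                              ref_spec = phantom_spec(1.5, 0.05,
                                                      id = "reference"),
                              dir = file.path(tempdir(), "phantom_study"),
                              lambda_step = 2, format = "bmp") {
  if (length(fx_fit) < 2) stop("fx_fit needs at least two frequencies")
  if (!all(fx_fit %in% fx_acquire)) {
    stop("fx_fit must be a subset of the acquired frequencies")
  }
  instrument$noise_sigma <- noise_sigma
  specs <- make_phantom_grid()
  slev <- attr(specs, "scattering_level")
  alev <- attr(specs, "absorption_level")
  bands <- instrument$bands
  lambda0 <- instrument$lambda0
  cfg <- inversion_config(fx_subset = fx_fit)

  ref_acq <- simulate_acquisition(ref_spec, instrument, fx_acquire, table,
                                  seed = seed, dir = dir,
                                  role = "reference", format = format)
  lambda_grid <- seq(400, 700, by = lambda_step)
  rows <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    acq <- simulate_acquisition(spec, instrument, fx_acquire, table,
                                seed = seed + k, dir = dir, format = format)
    manifest <- rbind(acq$manifest, ref_acq$manifest)
    maps <- process_acquisition(manifest, table, fx_acquire, ref_spec,
                                bands, config = cfg)
    sfds <- simulate_sfds_spectrum(spec, table, fx_list = fx_fit,
                                   lambda_grid = lambda_grid)
    mua_ref <- emulate_band_values(
      spectrum_curve(lambda_grid, sfds$mu_a_fit), bands)
    musp_ref <- emulate_band_values(
      spectrum_curve(lambda_grid, sfds$mu_s_prime_fit), bands)
    for (bname in names(bands)) {
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = spec$id, band = bname, lambda0 = lambda0[[bname]],
        property = c("mu_a", "mu_s_prime"),
        value_sfdi = c(maps[[bname]]$fov_mu_a,
                       maps[[bname]]$fov_mu_s_prime),
        value_reference = c(mua_ref[[bname]], musp_ref[[bname]]),
        absorption_level = alev[k], scattering_level = slev[k],
        stringsAsFactors = FALSE)
    }
  }
  comparison <- do.call(rbind, rows)
  reg <- lapply(c(mu_a = "mu_a", mu_s_prime = "mu_s_prime"), function(p) {
    d <- comparison[comparison$property == p, ]
    regression_stats(d$value_reference, d$value_sfdi)
  })
  structure(list(comparison = comparison, regression = reg,
                 settings = list(seed = seed, noise_sigma = noise_sigma,
                                 fx_acquire = fx_acquire, fx_fit = fx_fit,
                                 lambda_step = lambda_step)),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("phantom_study: %d comparison rows\n", nrow(x$comparison)))
  cat("  mu_a:      "); print(x$regression$mu_a)
  cat("  mu_s_prime:"); print(x$regression$mu_s_prime)
  invisible(x)
}

#' Export a phantom study as CSV (+ optional scatter plot)
#'
#' @param study A [run_phantom_study()] result.
#' @param comparison_csv,regression_csv Output CSV paths.
#' @param plot_file Optional PNG path for the scatter (regression and
#'   unity lines, clusters colored by generating level).
#' @export
export_phantom_study <- function(study, comparison_csv, regression_csv,
                                 plot_file = NULL) {
  write.csv(study$comparison, comparison_csv, row.names = FALSE)
  reg <- do.call(rbind, lapply(names(study$regression), function(p) {
    r <- study$regression[[p]]
    data.frame(property = p, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, rmse = r$rmse, n = r$n)
  }))
  write.csv(reg, regression_csv, row.names = FALSE)
  if (!is.null(plot_file)) plot_phantom_study(study, plot_file)
  invisible(study)
}

#' @rdname export_phantom_study
#' @export
plot_phantom_study <- function(study, plot_file) {
  grDevices::png(plot_file, width = 1200, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (p in c("mu_a", "mu_s_prime")) {
    d <- study$comparison[study$comparison$property == p, ]
    lev <- if (p == "mu_a") d$absorption_level else d$scattering_level
    graphics::plot(d$value_reference, d$value_sfdi, col = lev, pch = 16,
                   xlab = "reference (band-emulated SFDS)",
                   ylab = "SFDI (FOV mean)", main = p)
    graphics::abline(0, 1, lty = 3)
    r <- study$regression[[p]]
    graphics::abline(r$intercept, r$slope, lty = 2)
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "R^2 = %.3f, RMSE = %.3g", r$r_squared, r$rmse))
  }
  invisible(plot_file)
}
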