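#' Configuration for the optical-property inverse solver
#'
#' @param initial_guess An [optical_properties()] starting point.  Default
#'   (0.1, 1.5) mm^-1, the center of the physiological skin range.
#' @param mu_a_bounds,mu_s_prime_bounds Search box (mm^-1); the initial
#'   guess must lie inside.
#' @param ftol Absolute convergence tolerance on the objective.
#' @param xtol Convergence tolerance on the parameters (mm^-1).
#' @param max_iter Iteration cap; hitting it flags the pixel instead of
#'   raising.
#' @param fx_subset Spatial frequencies used for fitting (>= 2 required:
#'   separating absorption from scattering needs at least two).
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(initial_guess = optical_properties(0.1, 1.5),
                             mu_a_bounds = c(0.005, 0.5),
                             mu_s_prime_bounds = c(0.3, 5),
                             ftol = 1e-10, xtol = 1e-6, max_iter = 500L,
                             fx_subset = c(0, 0.05, 0.1)) {
  stopifnot(inherits(initial_guess, "optical_properties"))
  if (length(fx_subset) < 2) {
    stop("at least two spatial frequencies are required for inversion")
  }
  if (initial_guess$mu_a < mu_a_bounds[1] ||
      initial_guess$mu_a > mu_a_bounds[2] ||
      initial_guess$mu_s_prime < mu_s_prime_bounds[1] ||
      initial_guess$mu_s_prime > mu_s_prime_bounds[2]) {
    stop("initial guess must lie inside the bounds")
  }
  structure(list(initial_guess = initial_guess,
                 mu_a_bounds = mu_a_bounds,
                 mu_s_prime_bounds = mu_s_prime_bounds,
                 ftol = ftol, xtol = xtol, max_iter = as.integer(max_iter),
                 fx_subset = fx_subset),
            class = "inversion_config")
}

#' Misfit between measured and forward-model reflectance
#'
#' Sum over spatial frequencies of squared differences between the
#' measured Rd and the table lookup at the candidate properties.  Out of
#' bounds candidates return a large finite penalty, keeping the simplex
#' search inside the table domain.
#'
#' @param params An [optical_properties()] candidate.
#' @param rd_measured Measured Rd, one per `fx_list`.
#' @param fx_list Spatial frequencies (must be tabulated).
#' @param table A [build_table()] result.
#' @return Scalar misfit.
#' @export
objective <- function(params, rd_measured, fx_list, table) {
  stopifnot(length(rd_measured) == length(fx_list))
  pred <- tryCatch(lookup_rd(table, params, fx_list),
                   error = function(e) NULL)
  if (is.null(pred)) return(1e3)
  sum((rd_measured - pred)^2)
}

table_fx_slice <- function(table, fx_list) {
  kf <- match_fx(table$fx_grid, fx_list)
  as.vector(table$rd[, , kf, drop = FALSE])
}

#' Fit optical properties for a single pixel
#'
#' Nelder-Mead simplex minimization of [objective()] from the configured
#' initial guess; deterministic given inputs and config.  Non-positive or
#' non-finite measurements are flagged non-converged rather than raising.
#'
#' @param rd_measured Measured Rd per fx.
#' @param fx_list Spatial frequencies.
#' @param table A `reflectance_table`.
#' @param config An [inversion_config()].
#' @return List with `props` ([optical_properties()] or NULL), `residual`,
#'   `converged`.
#' @export
fit_pixel <- function(rd_measured, fx_list, table,
                      config = inversion_config(fx_subset = fx_list)) {
  stopifnot(inherits(config, "inversion_config"))
  if (length(fx_list) < 2) stop("at least two spatial frequencies required")
  fit <- cpp_fit_pixels(matrix(rd_measured, nrow = 1),
                        log(table$mu_a_grid), log(table$mu_s_prime_grid),
                        table_fx_slice(table, fx_list),
                        c(config$initial_guess$mu_a,
                          config$initial_guess$mu_s_prime),
                        c(config$mu_a_bounds, config$mu_s_prime_bounds),
                        config$ftol, config$xtol, config$max_iter)
  if (is.na(fit[1, 1])) {
    return(list(props = NULL, residual = NA_real_, converged = FALSE))
  }
  g <- table$metadata$g; n <- table$metadata$n
  list(props = optical_properties(max(fit[1, 1], 0), fit[1, 2],
                                  g = if (is.null(g)) 0.8 else g,
                                  n = if (is.null(n)) 1.4 else n),
       residual = fit[1, 3], converged = fit[1, 4] == 1)
}

#' Fit optical-property maps for a stack of Rd images
#'
#' Runs independent per-pixel Nelder-Mead fits (order-independent) for one
#' band and returns per-pixel maps plus the field-of-view means used for
#' homogeneous-phantom summaries.
#'
#' @param rd_maps List of Rd matrices, one per entry of `fx_list`, all the
#'   same shape (as produced by [calibrate()]).
#' @param fx_list Spatial frequencies matching `rd_maps`.
#' @param table A `reflectance_table`.
#' @param config An [inversion_config()].
#' @return An object of class `property_map`: matrices `mu_a_map`,
#'   `mu_s_prime_map`, `residuals`, logical `converged`, and the scalars
#'   `fov_mu_a`, `fov_mu_s_prime` (means over converged pixels).
#' @export
fit_image <- function(rd_maps, fx_list, table,
                      config = inversion_config(fx_subset = fx_list)) {
  stopifnot(is.list(rd_maps), length(rd_maps) == length(fx_list))
  dims <- dim(rd_maps[[1]])
  for (m in rd_maps) {
    if (!all(dim(m) == dims)) stop("all fx planes must share one shape")
  }
  rd_mat <- do.call(cbind, lapply(rd_maps, as.vector))
  fit <- cpp_fit_pixels(rd_mat,
                        log(table$mu_a_grid), log(table$mu_s_prime_grid),
                        table_fx_slice(table, fx_list),
                        c(config$initial_guess$mu_a,
                          config$initial_guess$mu_s_prime),
                        c(config$mu_a_bounds, config$mu_s_prime_bounds),
                        config$ftol, config$xtol, config$max_iter)
  conv <- matrix(fit[, 4] == 1, nrow = dims[1])
  mua <- matrix(fit[, 1], nrow = dims[1])
  musp <- matrix(fit[, 2], nrow = dims[1])
  structure(list(mu_a_map = mua, mu_s_prime_map = musp,
                 residuals = matrix(fit[, 3], nrow = dims[1]),
                 converged = conv,
                 fov_mu_a = mean(mua[conv]),
                 fov_mu_s_prime = mean(musp[conv])),
            class = "property_map")
}

#' @export
print.property_map <- function(x, ...) {
  cat(sprintf(
    "property_map %dx%d: FOV mu_a = %.4g, mu_s' = %.4g mm^-1 (%.1f%% converged)\n",
    nrow(x$mu_a_map), ncol(x$mu_a_map), x$fov_mu_a, x$fov_mu_s_prime,
    100 * mean(x$converged)))
  invisible(x)
}
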