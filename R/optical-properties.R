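#' Optical properties of a homogeneous turbid medium
#'
#' Bundle of the absorption coefficient, reduced scattering coefficient,
#' scattering anisotropy and internal refractive index that the forward
#' model and the inverse solver operate on.  All coefficients are in
#' mm^-1; `g` and `n` are dimensionless.
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s_prime Reduced scattering coefficient (mm^-1), > 0.
#' @param g Scattering anisotropy in `[0, 1)` (Henyey-Greenstein).
#' @param n Internal refractive index, >= 1 (outside medium is 1).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(0.05, 1.5)
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.8, n = 1.4) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L)
  if (is.na(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (is.na(mu_s_prime) || mu_s_prime <= 0) stop("mu_s_prime must be > 0")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (n < 1) stop("n must be >= 1")
  mu_s <- mu_s_prime / (1 - g)
  if (!is.finite(mu_s)) stop("derived mu_s = mu_s_prime/(1 - g) is not finite")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "optical_properties: mu_a = %g mm^-1, mu_s' = %g mm^-1 (g = %g, n = %g)\n",
    x$mu_a, x$mu_s_prime, x$g, x$n))
  invisible(x)
}
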