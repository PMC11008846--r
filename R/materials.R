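#' Density-modulus laws for femoral bone
#'
#' Empirical relations converting apparent bone mineral density (g/cm^3) to
#' elastic modulus (MPa): an affine law for cortical bone,
#' `E_c = -13450 + 14261 * rho`, and a power law for trabecular bone,
#' `E_t = 6950 * rho^1.49`. These document the material model behind the
#' finite-element stage that produced the strain surrogate; the reliability
#' pipeline itself works directly on the surrogate, so these laws do not feed
#' the probability-of-failure computation.
#'
#' @param kind `"cortical_linear"` or `"trabecular_power"`.
#' @param intercept,slope Affine coefficients (MPa; MPa per g/cm^3), cortical
#'   law only.
#' @param coefficient,exponent Power-law coefficients (MPa; dimensionless),
#'   trabecular law only. Both must be positive.
#'
#' @return An object of class `density_modulus_law`.
#' @examples
#' cortical_modulus(1.86)   # ~13075 MPa
#' trabecular_modulus(0.5)  # ~2475 MPa
#' @export
density_modulus_law <- function(kind = c("cortical_linear", "trabecular_power"),
                                intercept = -13450, slope = 14261,
                                coefficient = 6950, exponent = 1.49) {
  kind <- match.arg(kind)
  if (kind == "trabecular_power") {
    if (coefficient <= 0) stop("'coefficient' must be positive")
    if (exponent <= 0) stop("'exponent' must be positive")
    law <- list(kind = kind, coefficient = coefficient, exponent = exponent)
  } else {
    law <- list(kind = kind, intercept = intercept, slope = slope)
  }
  structure(law, class = "density_modulus_law")
}

#' @rdname density_modulus_law
#' @param density Apparent bone mineral density in g/cm^3. Must be positive
#'   for the cortical law (which is only physically meaningful near
#'   1.86 g/cm^3) and non-negative for the trabecular law.
#' @param law Optional law object; defaults to the published coefficients.
#' @export
cortical_modulus <- function(density, law = density_modulus_law("cortical_linear")) {
  stopifnot(inherits(law, "density_modulus_law"), law$kind == "cortical_linear")
  if (any(density <= 0)) stop("cortical density must be positive (g/cm^3)")
  e <- law$intercept + law$slope * density
  if (any(e < 0)) {
    warning("cortical modulus is negative below density ",
            signif(-law$intercept / law$slope, 5),
            " g/cm^3; the affine law is only intended near 1.86 g/cm^3")
  }
  e
}

#' @rdname density_modulus_law
#' @export
trabecular_modulus <- function(density,
                               law = density_modulus_law("trabecular_power")) {
  stopifnot(inherits(law, "density_modulus_law"), law$kind == "trabecular_power")
  if (any(density < 0)) stop("trabecular density must be non-negative (g/cm^3)")
  law$coefficient * density^law$exponent
}
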