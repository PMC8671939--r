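# Scalar binding and stability thermodynamics from dissociation constants
# and melting temperatures.

#' Binding free-energy difference from a Kd ratio
#'
#' `ddG = R * T * ln(kd_a / kd_b)` with R = 8.314 J mol^-1 K^-1, reported
#' in kJ/mol.  Positive when `kd_a` is the weaker binder.  For the
#' staurosporine (88 nM) vs UCN-01 (3.5 nM) pair at 298 K this evaluates
#' to ~8 kJ/mol.
#'
#' @param kd_a,kd_b Dissociation constants in the same units (> 0).
#' @param temperature_k Absolute temperature (default 298 K, the
#'   solution-experiment temperature).
#' @return Free-energy difference in kJ/mol.
#' @export
delta_delta_g <- function(kd_a, kd_b, temperature_k = 298) {
  if (any(kd_a <= 0) || any(kd_b <= 0)) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  stopifnot(temperature_k > 0)
  8.314 * temperature_k * log(kd_a / kd_b) / 1000
}

#' Affinity fold change
#'
#' @inheritParams delta_delta_g
#' @return `kd_a / kd_b` (dimensionless).
#' @export
fold_change <- function(kd_a, kd_b) {
  if (any(kd_a <= 0) || any(kd_b <= 0)) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  kd_a / kd_b
}

#' Thermal stability shift
#'
#' @param tm_free,tm_bound Melting temperatures (degrees C) of the free
#'   and ligand-bound protein.
#' @return `tm_bound - tm_free` in degrees C.
#' @export
delta_tm <- function(tm_free, tm_bound) {
  stopifnot(is.finite(tm_free), is.finite(tm_bound))
  tm_bound - tm_free
}
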