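# Headspace/dissolved partitioning of N2O in sealed serum bottles at
# solubility equilibrium, via the Bunsen absorption coefficient.

#' Serum-bottle geometry and N2O solubility
#'
#' Describes the culture vessel used to convert a headspace N2O amount into
#' a whole-bottle amount. The shipped default is 20 mL anoxic medium in a
#' 50 mL bottle (30 mL headspace) at 25 degrees C with a Bunsen absorption
#' coefficient of 0.544 (volume of gas dissolved per volume of liquid at
#' unit partial pressure).
#'
#' @param v_liquid Liquid volume, mL (> 0).
#' @param v_headspace Headspace volume, mL (> 0).
#' @param temperature Incubation temperature, degrees C (used only by the
#'   ideal-gas conversion of mixing ratios; the solubility coefficient is a
#'   configured constant, no temperature correlation is applied).
#' @param bunsen_alpha Bunsen absorption coefficient, dimensionless (>= 0).
#' @param pressure_atm Total headspace pressure, atm (assumed 1).
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(v_liquid = 20, v_headspace = 30,
                            temperature = 25, bunsen_alpha = 0.544,
                            pressure_atm = 1) {
  stopifnot(v_liquid > 0, v_headspace > 0, bunsen_alpha >= 0, pressure_atm > 0)
  structure(
    list(v_liquid = v_liquid, v_headspace = v_headspace,
         temperature = temperature, bunsen_alpha = bunsen_alpha,
         pressure_atm = pressure_atm),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> %.4g mL liquid / %.4g mL headspace, %.4g C, Bunsen alpha = %.4g, %.4g atm\n",
    x$v_liquid, x$v_headspace, x$temperature, x$bunsen_alpha, x$pressure_atm
  ))
  invisible(x)
}

#' Total per-bottle N2O from a headspace amount
#'
#' At solubility equilibrium the dissolved amount is
#' `alpha * v_liquid / v_headspace` times the headspace amount, so
#' `total = n_headspace * (1 + alpha * v_liquid / v_headspace)`.
#'
#' @param n_headspace N2O in the headspace, umol (>= 0). Vectorised.
#' @param geom A [vessel_geometry()].
#' @return Total (headspace + dissolved) N2O, umol.
#' @examples
#' total_n2o(1, vessel_geometry()) # 1.3627 umol
#' @export
total_n2o <- function(n_headspace, geom = vessel_geometry()) {
  if (any(n_headspace < 0, na.rm = TRUE)) {
    stop("headspace N2O amount must be >= 0", call. = FALSE)
  }
  n_headspace * (1 + geom$bunsen_alpha * geom$v_liquid / geom$v_headspace)
}

#' Equilibrium fraction of N2O dissolved in the medium
#'
#' @param geom A [vessel_geometry()].
#' @return `alpha * v_liquid / (v_headspace + alpha * v_liquid)`, in `[0, 1)`.
#' @export
dissolved_fraction <- function(geom = vessel_geometry()) {
  a <- geom$bunsen_alpha * geom$v_liquid
  a / (geom$v_headspace + a)
}

#' Convert a GC mixing ratio to a headspace amount
#'
#' Ideal-gas conversion of a gas-chromatograph N2O reading (ppmv) to umol in
#' the headspace at the vessel temperature and pressure.
#'
#' @param ppmv Mixing ratio, parts per million by volume. Vectorised.
#' @param geom A [vessel_geometry()].
#' @return Headspace N2O, umol.
#' @export
ppmv_to_umol <- function(ppmv, geom = vessel_geometry()) {
  if (any(ppmv < 0, na.rm = TRUE)) stop("mixing ratio must be >= 0", call. = FALSE)
  R <- 0.0820573661 # L atm / (mol K)
  n_total_mol <- geom$pressure_atm * (geom$v_headspace / 1000) /
    (R * (geom$temperature + 273.15))
  ppmv * 1e-6 * n_total_mol * 1e6
}
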