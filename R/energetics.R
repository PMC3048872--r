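# Structure-energetics correlations: empirical linear relations mapping
# the apolar/polar accessible-surface-area change upon unfolding to the
# unfolding heat-capacity change and the unfolding enthalpy at a 60 degC
# reference temperature, with Kirchhoff extrapolation (constant dCp) to
# any other temperature. Coefficients (cal mol^-1 K^-1 A^-2 for dCp,
# cal mol^-1 A^-2 for dH60) follow the established surface-area
# parameterization of protein unfolding energetics.

.DCP_AP <- 0.45    # cal K^-1 mol^-1 per A^2 apolar
.DCP_POL <- -0.26  # cal K^-1 mol^-1 per A^2 polar
.DH60_AP <- -8.44  # cal mol^-1 per A^2 apolar
.DH60_POL <- 31.4  # cal mol^-1 per A^2 polar

#' Predicted unfolding heat-capacity change from surface-area changes
#'
#' \eqn{\Delta C_p = (0.45\,\Delta ASA_{ap} - 0.26\,\Delta ASA_{pol})/1000}
#' kcal K^-1 mol^-1: burial of apolar surface raises the unfolding heat
#' capacity, burial of polar surface lowers it.
#'
#' @param dasa_ap apolar surface-area change upon unfolding, angstrom^2.
#' @param dasa_pol polar surface-area change, angstrom^2.
#' @return Heat-capacity change, kcal K^-1 mol^-1.
#' @examples
#' predict_dcp(18746, 10598)  # ~5.7
#' @export
predict_dcp <- function(dasa_ap, dasa_pol) {
  (.DCP_AP * dasa_ap + .DCP_POL * dasa_pol) / 1000
}

#' Predicted unfolding enthalpy at 60 degrees Celsius
#'
#' \eqn{\Delta H(60) = (31.4\,\Delta ASA_{pol} - 8.44\,\Delta ASA_{ap})/1000}
#' kcal/mol, the reference-temperature enthalpy of the surface-area
#' parameterization.
#'
#' @inheritParams predict_dcp
#' @return Enthalpy, kcal/mol.
#' @examples
#' predict_dh60(18746, 10598)  # ~174.5
#' @export
predict_dh60 <- function(dasa_ap, dasa_pol) {
  (.DH60_POL * dasa_pol + .DH60_AP * dasa_ap) / 1000
}

#' Kirchhoff extrapolation of the unfolding enthalpy
#'
#' \eqn{\Delta H(T) = \Delta H(60) + \Delta C_p (T - 60)} with constant
#' heat-capacity change.
#'
#' @param dh60 enthalpy at 60 degC, kcal/mol.
#' @param dcp heat-capacity change, kcal K^-1 mol^-1.
#' @param t target temperature, degC.
#' @return Enthalpy at `t`, kcal/mol.
#' @export
dh_at_temperature <- function(dh60, dcp, t) {
  dh60 + dcp * (t - 60)
}

#' Residual-structure index
#'
#' Ratio of the experimentally measured unfolding enthalpy to the
#' structure-based prediction for complete unfolding. Values well below
#' one indicate that a substantial amount of ordered structure persists
#' in the thermally denatured state.
#'
#' @param dh_exp experimental enthalpy, kcal/mol.
#' @param dh_calc predicted enthalpy for complete unfolding, kcal/mol
#'   (must be positive).
#' @return Dimensionless fraction.
#' @export
residual_structure_index <- function(dh_exp, dh_calc) {
  stopifnot_positive(dh_calc, "dh_calc")
  dh_exp / dh_calc
}

#' Full energetics prediction from surface-area changes
#'
#' Combines [predict_dcp()], [predict_dh60()] and [dh_at_temperature()]
#' into the standard per-structure prediction block: surface-area
#' changes, heat-capacity change, enthalpy at 60 degC and enthalpy
#' extrapolated to the transition temperature.
#'
#' @inheritParams predict_dcp
#' @param tm transition temperature, degC.
#' @param dh_exp optional experimental enthalpy (kcal/mol); when given,
#'   the residual-structure index is included.
#' @return An object of class `energetics_prediction`.
#' @examples
#' predict_energetics(18746, 10598, tm = 71)
#' @export
predict_energetics <- function(dasa_ap, dasa_pol, tm, dh_exp = NULL) {
  dcp <- predict_dcp(dasa_ap, dasa_pol)
  dh60 <- predict_dh60(dasa_ap, dasa_pol)
  dhtm <- dh_at_temperature(dh60, dcp, tm)
  structure(list(
    dasa_ap = dasa_ap, dasa_pol = dasa_pol,
    dcp_calc = dcp, dh_calc_60 = dh60, tm = tm, dh_calc_at_tm = dhtm,
    residual_structure = if (!is.null(dh_exp))
      residual_structure_index(dh_exp, dhtm) else NULL),
    class = "energetics_prediction")
}

#' @export
print.energetics_prediction <- function(x, ...) {
  cat("Structure-energetics prediction\n")
  cat(sprintf("  dASA apolar / polar : %8.0f / %8.0f A^2\n",
              x$dasa_ap, x$dasa_pol))
  cat(sprintf("  dCp_calc            : %8.1f kcal/K/mol\n", x$dcp_calc))
  cat(sprintf("  dH_calc(60 degC)    : %8.1f kcal/mol\n", x$dh_calc_60))
  cat(sprintf("  dH_calc(Tm = %.1f)  : %8.1f kcal/mol\n",
              x$tm, x$dh_calc_at_tm))
  if (!is.null(x$residual_structure)) {
    cat(sprintf("  dH_exp / dH_calc    : %8.2f\n", x$residual_structure))
  }
  invisible(x)
}
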