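#' Two-state unfolding parameters
#'
#' Container for the three parameters of the two-state excess heat-capacity
#' model: the transition temperature, the calorimetric enthalpy (peak area)
#' and the van't Hoff enthalpy (transition sharpness). A calorimetric to
#' van't Hoff ratio near one indicates a two-state transition of the
#' monomer.
#'
#' @param tm transition temperature, degrees Celsius.
#' @param dh_cal calorimetric enthalpy, kcal/mol; must be positive
#'   (unfolding is endothermic).
#' @param dh_vh van't Hoff enthalpy, kcal/mol; must be positive.
#' @return An object of class `two_state_params`.
#' @examples
#' two_state_params(tm = 62.5, dh_cal = 111.6, dh_vh = 96.3)
#' @export
two_state_params <- function(tm, dh_cal, dh_vh) {
  stopifnot_positive(celsius_to_kelvin(tm), "tm (in kelvin)")
  stopifnot_positive(dh_cal, "dh_cal")
  stopifnot_positive(dh_vh, "dh_vh")
  structure(list(tm = tm, dh_cal = dh_cal, dh_vh = dh_vh),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "Two-state parameters: Tm = %.2f degC, dH_cal = %.1f kcal/mol, dH_vH = %.1f kcal/mol\n",
    x$tm, x$dh_cal, x$dh_vh))
  invisible(x)
}

#' Apparent two-state parameters for a CD melt
#'
#' Parameters of a sigmoidal circular-dichroism melt with linearly sloping
#' native and denatured baselines. The unfolded fraction follows a van't
#' Hoff two-state model with its own apparent midpoint and enthalpy,
#' independent of any calorimetric fit of the same protein (optical and
#' calorimetric probes may report different apparent midpoints).
#'
#' @param tm_app apparent midpoint, degrees Celsius.
#' @param dh_vh_app apparent van't Hoff enthalpy, kcal/mol.
#' @param native numeric of length 2: intercept and slope (per degC) of the
#'   pre-transition signal baseline, in signal units.
#' @param denatured numeric of length 2: intercept and slope of the
#'   post-transition baseline.
#' @return An object of class `cd_melt_params`.
#' @export
cd_melt_params <- function(tm_app, dh_vh_app,
                           native = c(0, 0), denatured = c(1, 0)) {
  stopifnot_positive(celsius_to_kelvin(tm_app), "tm_app (in kelvin)")
  stopifnot_positive(dh_vh_app, "dh_vh_app")
  stopifnot(length(native) == 2, length(denatured) == 2,
            all(is.finite(c(native, denatured))))
  structure(list(tm_app = tm_app, dh_vh_app = dh_vh_app,
                 native = as.numeric(native),
                 denatured = as.numeric(denatured)),
            class = "cd_melt_params")
}

#' @export
print.cd_melt_params <- function(x, ...) {
  cat(sprintf("CD melt parameters: Tm_app = %.2f degC, dH_vH(app) = %.1f kcal/mol\n",
              x$tm_app, x$dh_vh_app))
  cat(sprintf("  native baseline: %.4g + %.4g*T; denatured: %.4g + %.4g*T\n",
              x$native[1], x$native[2], x$denatured[1], x$denatured[2]))
  invisible(x)
}

#' Ligand-linkage parameters for thermal-shift analysis
#'
#' Single-site binding-linkage model: a ligand that binds only the native
#' state raises the melting temperature with increasing concentration.
#' The dissociation constant is referenced to the ligand-free transition
#' temperature and treated as temperature independent.
#'
#' @param tm0 ligand-free transition temperature, degrees Celsius.
#' @param dh0 unfolding enthalpy at `tm0`, kcal/mol.
#' @param kd ligand dissociation constant, mol/L.
#' @return An object of class `linkage_params`.
#' @export
linkage_params <- function(tm0, dh0, kd) {
  stopifnot_positive(celsius_to_kelvin(tm0), "tm0 (in kelvin)")
  stopifnot_positive(dh0, "dh0")
  stopifnot_positive(kd, "kd")
  structure(list(tm0 = tm0, dh0 = dh0, kd = kd), class = "linkage_params")
}

#' @export
print.linkage_params <- function(x, ...) {
  cat(sprintf("Linkage parameters: Tm0 = %.2f degC, dH0 = %.1f kcal/mol, Kd = %.3g M\n",
              x$tm0, x$dh0, x$kd))
  invisible(x)
}
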