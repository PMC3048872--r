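# Closed-form two-state thermodynamic models.
#
# The excess molar heat capacity of a two-state unfolding transition is
#
#   Cp_ex(T) = dH * dH_vH * K(T) / (R * T^2 * (1 + K(T))^2)
#
# with the van't Hoff equilibrium constant
#
#   K(T) = exp[(dH_vH / R) * (1/Tm - 1/T)]
#
# where dH is the calorimetric enthalpy (the peak area), dH_vH the van't
# Hoff enthalpy (the transition sharpness), R the gas constant and T the
# absolute temperature. The unfolded fraction is theta = K / (1 + K), so
# Cp_ex = dH * dtheta/dT and the curve integrates to dH exactly.
#
# A heat-capacity increment of the transition itself (a dCp step between
# the folded and unfolded trends) is handled upstream by the chemical
# baseline removal, not by these model functions.

#' Van't Hoff equilibrium constant of a two-state transition
#'
#' \eqn{K(T) = \exp[(\Delta H^{VH}/R)(1/T_m - 1/T)]}, with temperatures
#' converted to kelvin internally. \eqn{K(T_m) = 1} by construction, and
#' \eqn{K} is strictly increasing in temperature for positive van't Hoff
#' enthalpy.
#'
#' @param t temperature, degrees Celsius (vectorized).
#' @param params a [two_state_params()] object (only `tm` and `dh_vh` are
#'   used).
#' @return Dimensionless equilibrium constant, same length as `t`.
#' @examples
#' p <- two_state_params(62.5, 111.6, 96.3)
#' equilibrium_constant(62.5, p)  # 1 at the midpoint
#' @export
equilibrium_constant <- function(t, params) {
  tk <- celsius_to_kelvin(t)
  stopifnot_positive(tk, "t (in kelvin)")
  tmk <- celsius_to_kelvin(params$tm)
  exp((params$dh_vh * 1000 / .R_CAL) * (1 / tmk - 1 / tk))
}

#' Unfolded fraction of a two-state transition
#'
#' \eqn{\theta(T) = K/(1+K)}; equals 0.5 at the transition temperature and
#' is monotone non-decreasing in temperature.
#'
#' @inheritParams equilibrium_constant
#' @return Fraction in \[0, 1\], same length as `t`.
#' @export
unfolded_fraction <- function(t, params) {
  k <- equilibrium_constant(t, params)
  # k/(1+k) overflows for very large k; use the stable logistic form
  ifelse(is.infinite(k), 1, k / (1 + k))
}

#' Two-state excess molar heat capacity
#'
#' \eqn{C_p^{ex}(T) = \Delta H \,\Delta H^{VH} K / [R T^2 (1+K)^2]}. The
#' curve is non-negative with a single maximum at the transition
#' temperature, where it equals
#' \eqn{\Delta H\,\Delta H^{VH} / (4 R T_m^2)}, and its integral over
#' temperature is the calorimetric enthalpy.
#'
#' @inheritParams equilibrium_constant
#' @param params a [two_state_params()] object.
#' @return Excess heat capacity, kcal mol^-1 K^-1, same length as `t`.
#' @examples
#' p <- two_state_params(62.5, 111.6, 96.3)
#' two_state_excess_cp(62.5, p)  # peak height, ~12 kcal/mol/K
#' @export
two_state_excess_cp <- function(t, params) {
  tk <- celsius_to_kelvin(t)
  stopifnot_positive(tk, "t (in kelvin)")
  stopifnot_positive(params$dh_cal, "dh_cal")
  k <- equilibrium_constant(t, params)
  # in cal: dh*dhvh*1e6 * k / (R tk^2 (1+k)^2); report kcal/(mol K)
  cp <- params$dh_cal * params$dh_vh * 1e6 * k /
    (.R_CAL * tk^2 * (1 + k)^2)
  ifelse(is.infinite(k), 0, cp) / 1000
}

#' Two-state CD melt signal with sloping baselines
#'
#' Optical melting curve: the observed signal is the population-weighted
#' average of linear native and denatured baselines,
#' \eqn{s(T) = (1-\theta) b_N(T) + \theta b_D(T)}, with the unfolded
#' fraction \eqn{\theta} from a van't Hoff two-state model parameterized by
#' the apparent midpoint and apparent van't Hoff enthalpy.
#'
#' @param t temperature, degrees Celsius (vectorized).
#' @param params a [cd_melt_params()] object.
#' @return Signal in the baseline units, same length as `t`.
#' @export
cd_two_state_signal <- function(t, params) {
  theta <- unfolded_fraction(
    t, two_state_params(params$tm_app, params$dh_vh_app, params$dh_vh_app))
  bn <- params$native[1] + params$native[2] * t
  bd <- params$denatured[1] + params$denatured[2] * t
  (1 - theta) * bn + theta * bd
}

#' Ligand-shifted melting temperature (single-site linkage)
#'
#' For a ligand binding only the native state with temperature-independent
#' dissociation constant \eqn{K_d}, the melting temperature shifts
#' according to
#' \deqn{1/T_{m,0} - 1/T_m(L) = (R/\Delta H_0)\,\ln(1 + L/K_d),}
#' which is solved in closed form for \eqn{T_m(L)}. The shift is zero at
#' zero ligand and strictly increasing in ligand concentration.
#'
#' @param ligand_conc free ligand concentration, mol/L (vectorized,
#'   non-negative).
#' @param params a [linkage_params()] object.
#' @return Shifted melting temperature, degrees Celsius.
#' @examples
#' lp <- linkage_params(tm0 = 62.5, dh0 = 111.6, kd = 1e-6)
#' ligand_shifted_tm(c(0, 1e-6, 1e-4), lp)
#' @export
ligand_shifted_tm <- function(ligand_conc, params) {
  if (!all(is.finite(ligand_conc)) || any(ligand_conc < 0)) {
    dscfit_stop("`ligand_conc` must be finite and non-negative",
                "dscfit_invalid_input")
  }
  tm0k <- celsius_to_kelvin(params$tm0)
  inv <- 1 / tm0k -
    (.R_CAL / (params$dh0 * 1000)) * log1p(ligand_conc / params$kd)
  kelvin_to_celsius(1 / inv)
}
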