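#' Valve blood inertance
#'
#' `L = rho * l / A` with the inflow length set to the instantaneous valve
#' diameter, giving `L = 2 rho / (pi r)`; evaluated in CGS and converted to
#' mmHg s^2/ml.
#'
#' @param a_eff Effective orifice area, cm^2 (> 0).
#' @param rho Blood density, g/cm^3.
#' @return Inertance, mmHg s^2/ml.
#' @examples
#' valve_inertance(pi, 1.060)  # r = 1 cm
#' @export
valve_inertance <- function(a_eff, rho = 1.060) {
  if (a_eff <= 0) stop("valve_inertance: a_eff must be positive")
  cpp_valve_inertance(a_eff, rho)
}

#' Instantaneous valve pressure gradient
#'
#' Bernoulli orifice resistance plus an inertial term:
#' `dp = rho/(2 A^2) q |q| + L(A) dq/dt`, converted to mmHg.  The
#' Bernoulli term dominates diastolic mitral inflow; the inertial term
#' shapes the flow transients at opening and closure.
#'
#' @param q Flow, ml/s (signed, forward positive).
#' @param dq_dt Flow acceleration, ml/s^2.
#' @param a_eff Effective orifice area, cm^2 (> 0).
#' @param rho Blood density, g/cm^3.
#' @return Pressure gradient, mmHg.
#' @export
valve_gradient <- function(q, dq_dt, a_eff, rho = 1.060) {
  if (a_eff <= 0) stop("valve_gradient: a_eff must be positive")
  cpp_valve_gradient(q, dq_dt, a_eff, rho)
}

#' Gradual valve opening and closing
#'
#' One explicit update of the open fraction `zeta`, driven by the pressure
#' gradient across the valve: `dzeta/dt = k_open * dp * (1 - zeta)` for
#' positive gradients and `k_close * dp * zeta` for negative ones; the
#' result is clamped to `[0, 1]`.
#'
#' @param zeta Current open fraction in `[0, 1]`.
#' @param dp_across Pressure gradient across the valve, mmHg.
#' @param dt Time step, s.
#' @param k_open,k_close Rate constants, 1/(mmHg s).
#' @return Updated open fraction in `[0, 1]`.
#' @export
update_valve_opening <- function(zeta, dp_across, dt, k_open, k_close) {
  if (k_open <= 0 || k_close <= 0)
    stop("update_valve_opening: rate constants must be positive")
  z <- zeta + dt * cpp_zeta_rate(zeta, dp_across, k_open, k_close)
  min(max(z, 0), 1)
}

#' Gorlin orifice shunt flow
#'
#' Empirical orifice equation `Q = C A sqrt(2 g dP) = 44.3 A sqrt(dP)`
#' with the Gorlin constant `C = 1` and `g = 980 cm/s^2`; signed and
#' bidirectional.  Used for atrial and ventricular septal defects and a
#' persistent ductus arteriosus.
#'
#' @param area Defect area, cm^2 (>= 0).
#' @param dp Pressure difference, mmHg (vectorised).
#' @param gorlin_c Empirical Gorlin constant.
#' @param g Gravitational acceleration, cm/s^2.
#' @return Flow, ml/s, with the sign of `dp`.
#' @examples
#' shunt_flow(1, 1)   # 44.3 ml/s
#' @export
shunt_flow <- function(area, dp, gorlin_c = 1, g = 980) {
  if (area < 0) stop("shunt_flow: area must be non-negative")
  cpp_gorlin_flow(area, dp, gorlin_c, g)
}
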