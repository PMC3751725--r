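#' Normalised Double-Hill activation function
#'
#' The activation waveform of a cardiac chamber: the product of a rising
#' and a falling Hill sigmoid over the cardiac cycle, rescaled so that its
#' single interior maximum is exactly 1.  The normalisation constant is
#' recomputed for every parameter combination (a dense scan refined by
#' ternary search), so changing the shape constants or the period never
#' changes the peak value.
#'
#' @param t_cycle Time within the cycle, seconds, `0 <= t_cycle < period`.
#'   May be a vector.
#' @param period Cycle length, seconds (`60 / heart rate`).
#' @param alpha1,alpha2 Half-activation points of the rising and falling
#'   sigmoids, expressed as fractions of the period.
#' @param n1,n2 Hill exponents of the rising and falling sigmoids.
#' @return Activation values in `[0, 1]`; exactly 0 at `t_cycle = 0`.
#' @examples
#' double_hill_activation(0.3, 0.833, 0.303, 0.508, 1.32, 27.4)
#' @export
double_hill_activation <- function(t_cycle, period, alpha1, alpha2,
                                   n1 = 1.32, n2 = 27.4) {
  if (period <= 0) stop("double_hill_activation: period must be positive")
  if (alpha1 <= 0 || alpha2 <= 0)
    stop("double_hill_activation: alpha1 and alpha2 must be positive")
  cpp_dh_activation(t_cycle / period, alpha1, alpha2, n1, n2)
}

#' Load-dependent effective maximum elastance (Starling roll-off)
#'
#' Returns `e_max` unchanged at or below the threshold volume and a smooth,
#' monotone, saturating reduction above it, bending the end-systolic
#' pressure-volume relation downwards during volume overload.
#'
#' @param e_max Maximum (end-systolic) elastance, mmHg/ml.
#' @param v Chamber volume, ml (vectorised).
#' @param starling_params List with `v_th` (threshold volume, ml), `width`
#'   (roll-off scale, ml) and `depth` (maximal fractional reduction,
#'   `0 <= depth < 1`).
#' @return Effective maximum elastance, mmHg/ml.
#' @export
effective_emax <- function(e_max, v, starling_params) {
  e_max * cpp_starling_mult(v, starling_params$v_th, starling_params$width,
                            starling_params$depth)
}

#' Nonlinear passive (end-diastolic) chamber pressure
#'
#' Exponential end-diastolic pressure-volume relation
#' `p = e_min * phi * (exp((v - v0)/phi) - 1)`: zero at the unstressed
#' volume, slope `e_min` there, and convex stiffening with dilatation.
#'
#' @param v Chamber volume, ml (vectorised).
#' @param e_min Basal passive stiffness, mmHg/ml (slope at `v0`).
#' @param v0 Passive unstressed volume, ml.
#' @param phi Exponential volume scale, ml.
#' @return Passive pressure, mmHg.
#' @export
passive_pressure <- function(v, e_min, v0, phi) {
  cpp_passive_pressure(v, e_min, v0, phi)
}

#' Instantaneous chamber pressure
#'
#' Blends the active and passive limbs with the activation value as a
#' convex weight and adds the viscous wall term:
#' `p = a * e_max_eff(v) * (v - v0) + (1 - a) * p_passive(v) +
#' r_wall * dv/dt` (before septal, pericardial and intrathoracic
#' additions).
#'
#' @param v Chamber volume, ml.
#' @param activation Activation in `[0, 1]`.
#' @param e_max,e_min Maximum and basal elastance, mmHg/ml.
#' @param v0 Active unstressed volume (ESPVR intercept), ml.
#' @param v0_dia,phi_dia Passive unstressed volume and exponential scale,
#'   ml.
#' @param dv_dt Rate of volume change, ml/s.
#' @param r_wall Viscous wall resistance, mmHg s/ml.
#' @param starling_params Optional Starling roll-off constants (see
#'   [effective_emax()]); `NULL` disables the roll-off.
#' @return Chamber pressure, mmHg.
#' @export
chamber_pressure <- function(v, activation, e_max, e_min, v0, v0_dia,
                             phi_dia, dv_dt = 0, r_wall = 0,
                             starling_params = NULL) {
  em <- if (is.null(starling_params)) e_max
        else effective_emax(e_max, v, starling_params)
  activation * em * (v - v0) +
    (1 - activation) * passive_pressure(v, e_min, v0_dia, phi_dia) +
    r_wall * dv_dt
}

#' Septal pressure transmission between the ventricles
#'
#' Left ventricular pressure with interventricular coupling through a
#' muscular septum whose stiffness scales with the instantaneous left
#' ventricular elastance (`Esv = esv0 * elv`):
#' `plv = Esv/(Esv + elv) * elv * vlv + elv/(Esv + elv) * prv`.
#' The symmetric relation (swap left/right roles) yields the right
#' ventricular pressure; the atrial septum is treated the same way with a
#' constant stiffness.
#'
#' @param elv_t Instantaneous left ventricular elastance, mmHg/ml (> 0).
#' @param vlv Left ventricular volume, ml.
#' @param prv Right ventricular pressure, mmHg.
#' @param esv0 Dimensionless septal stiffness constant.
#' @return Coupled left ventricular pressure, mmHg.
#' @export
septal_coupled_pressure <- function(elv_t, vlv, prv, esv0) {
  if (elv_t <= 0) stop("septal_coupled_pressure: elv_t must be positive")
  esv <- esv0 * elv_t
  (esv / (esv + elv_t)) * elv_t * vlv + (elv_t / (esv + elv_t)) * prv
}

#' Pericardial pressure
#'
#' Exponential pericardial pressure-volume relation
#' `p = p_min + p_scale * exp((v - v_pc0)/phi)`; the minimum may be
#' negative, as measured experimentally during hypovolemia or
#' intrathoracic pressure changes.
#'
#' @param v_heart_total Total contained volume (chambers, myocardium,
#'   pericardial coronary blood), ml (vectorised).
#' @param p_min Asymptotic minimal pressure, mmHg (may be negative).
#' @param p_scale Pressure scale of the exponential, mmHg.
#' @param v_pc0 Pericardial volume constant, ml.
#' @param phi Exponential width, ml.
#' @return Pericardial pressure, mmHg.
#' @export
pericardial_pressure <- function(v_heart_total, p_min, p_scale, v_pc0,
                                 phi) {
  cpp_pericardial_pressure(v_heart_total, p_min, p_scale, v_pc0, phi)
}

#' Schematic ECG trace
#'
#' Weighted sum of the four chamber activation functions advanced by the
#' electromechanical delay (electrical activity precedes mechanical
#' activation by 60 ms by default).  Display-only: the trace never feeds
#' back into the simulated physiology.
#'
#' @param t Times, s (vectorised).
#' @param period Cycle length, s.
#' @param chambers List of four chamber parameter lists, each with
#'   `alpha1`, `alpha2`, `n1`, `n2`, `onset` (s).
#' @param weights Numeric vector of four lead weights.
#' @param delay Electromechanical delay, s.
#' @return ECG amplitude, arbitrary units.
#' @export
ecg_trace <- function(t, period, chambers, weights, delay = 0.06) {
  stopifnot(length(chambers) == 4, length(weights) == 4)
  out <- numeric(length(t))
  for (i in seq_len(4)) {
    ch <- chambers[[i]]
    phi <- ((t + delay - ch$onset) / period) %% 1
    out <- out + weights[i] *
      cpp_dh_activation(phi, ch$alpha1, ch$alpha2, ch$n1, ch$n2)
  }
  out
}
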