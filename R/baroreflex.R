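#' Baroreceptor reflex update
#'
#' One update of the arterial baroreflex: the sensed mean arterial
#' pressure is low-pass filtered with time constant `tau`, the fractional
#' error from the setpoint drives three bounded linear actuator
#' multipliers (heart rate, ventricular maximum elastance, systemic
#' arteriolar resistance).  This mirrors the in-solver controller; with
#' the reflex disabled all multipliers are exactly 1 and the solver output
#' is bit-identical to a run without the module.
#'
#' @param map Sensed arterial pressure, mmHg.
#' @param filtered Current filtered pressure, mmHg.
#' @param dt Time step, s.
#' @param params Baroreflex parameter list: `setpoint` (mmHg), `tau` (s),
#'   `gain_hr`, `gain_emax`, `gain_res` (per fractional mmHg error),
#'   `mult_min`, `mult_max` (actuator limits bracketing 1).
#' @return List with `filtered` (updated filter state) and `multipliers`
#'   (named vector `hr`, `emax`, `resistance`).
#' @export
reflex_update <- function(map, filtered, dt, params) {
  stopifnot(params$tau > 0, params$mult_min <= 1, params$mult_max >= 1)
  f <- filtered + dt * (map - filtered) / params$tau
  ef <- (params$setpoint - f) / params$setpoint
  clamp <- function(m) min(max(m, params$mult_min), params$mult_max)
  list(filtered = f,
       multipliers = c(hr = clamp(1 + params$gain_hr * ef),
                       emax = clamp(1 + params$gain_emax * ef),
                       resistance = clamp(1 + params$gain_res * ef)))
}
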