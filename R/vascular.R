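#' Vascular segment base properties at normal mean pressure
#'
#' Poiseuille resistance, blood inertance and wall elastance of a lumped
#' compartment of `n` identical parallel vessels:
#' `R0 = 8 eta l / (pi r0^4 n)`, `I0 = rho l / (pi r0^2 n)` (converted
#' from CGS to mmHg s^2/ml) and `E0 = Y_inc h / (2 pi r0^3 l n)`.
#'
#' @param eta Blood viscosity, mmHg s.
#' @param rho Blood density, g/cm^3.
#' @param y_inc Incremental Young's modulus, mmHg.
#' @param l,r0,h Length, radius and wall thickness of one vessel, cm
#'   (radius at the segment's normal mean pressure).
#' @param n Number of parallel vessels lumped into the segment.
#' @return `base_resistance`: mmHg s/ml; `base_inertance`: mmHg s^2/ml;
#'   `base_elastance`: mmHg/ml.
#' @name segment_base
NULL

#' @rdname segment_base
#' @export
base_resistance <- function(eta, l, r0, n = 1) {
  stopifnot(eta > 0, l > 0, r0 > 0, n > 0)
  cpp_base_resistance(eta, l, r0, n)
}

#' @rdname segment_base
#' @export
base_inertance <- function(rho, l, r0, n = 1) {
  stopifnot(rho >= 0, l > 0, r0 > 0, n > 0)
  cpp_base_inertance(rho, l, r0, n)
}

#' @rdname segment_base
#' @export
base_elastance <- function(y_inc, h, r0, l, n = 1) {
  stopifnot(y_inc > 0, h > 0, r0 > 0, l > 0, n > 0)
  cpp_base_elastance(y_inc, h, r0, l, n)
}

#' Transmural pressure of a vascular segment
#'
#' Anchored exponential pressure-volume relation
#' `p(v) = p0 * exp((e0/p0) (v - v0_seg))`, which passes through the
#' normal mean pressure `p0` at the reference volume with slope `e0` and
#' stiffens with progressive distension.  `linear = TRUE` selects the
#' linearised relation `p0 + e0 (v - v0_seg)` (used by Windkessel oracle
#' fixtures).
#'
#' @param v Segment volume, ml (vectorised).
#' @param v0_seg Reference volume at normal mean pressure, ml.
#' @param p0 Normal mean pressure, mmHg.
#' @param e0 Elastance at the reference point, mmHg/ml.
#' @param linear Use the linearised relation instead.
#' @return Transmural pressure, mmHg.
#' @export
transmural_pressure <- function(v, v0_seg, p0, e0, linear = FALSE) {
  stopifnot(p0 > 0, e0 > 0)
  cpp_transmural_pressure(v, v0_seg, p0, e0, linear)
}

#' Instantaneous segment properties
#'
#' Re-evaluates resistance, inertance, elastance and wall damping at the
#' current volume, assuming constant vessel length and wall thickness so
#' the radius scales as `sqrt(v / v_ref)`: `R = R0 (v_ref/v)^2`,
#' `I = I0 (v_ref/v)`, `E = E0 (v/v_ref)^(-3/2)`,
#' `Omega = lambda sqrt(I E)`.
#'
#' @param state List with `v` (current volume, ml), `v_ref` (reference
#'   volume, ml), `r0`, `i0`, `e0` (base properties) and `lambda`
#'   (damping scale factor).
#' @return Named numeric vector `r_now`, `i_now`, `e_now`, `omega_now`.
#' @export
update_segment_properties <- function(state) {
  if (state$v <= 0)
    stop("update_segment_properties: non-positive volume (collapse is not modelled)")
  cpp_segment_now(state$v, state$v_ref, state$r0, state$i0, state$e0,
                  state$lambda)
}

#' Viscoelastic wall damping
#'
#' Resistance in series with the compliance branch (in parallel with the
#' blood flow), `Omega = lambda * sqrt(I E)` — the characteristic-impedance
#' form scaled by the damping factor `lambda`; it damps the flow pulse
#' without affecting total peripheral resistance.
#'
#' @param i_now Instantaneous inertance, mmHg s^2/ml.
#' @param e_now Instantaneous elastance, mmHg/ml.
#' @param lambda Damping scale factor in `[0, 1]`; values near zero leave
#'   the wall undamped and lead to numerical ringing.
#' @return Damping resistance, mmHg s/ml.
#' @export
wall_damping <- function(i_now, e_now, lambda) {
  if (lambda < 0 || lambda > 1)
    stop("wall_damping: lambda must be in [0, 1]")
  cpp_wall_damping(i_now, e_now, lambda)
}
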