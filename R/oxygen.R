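#' Blood oxygen content
#'
#' `C = 0.0000136 * Hb * Sat * Volume` with hemoglobin in g/l, saturation
#' in percent and volume in ml — the clinical catheterisation-laboratory
#' convention (about 183 ml O2 per litre of arterial blood at Hb 140 g/l
#' and 96.2 % saturation).  Physically dissolved oxygen is not included.
#'
#' @param hb Hemoglobin, g/l.
#' @param sat Oxygen saturation, percent.
#' @param volume Blood volume, ml.
#' @return Oxygen content, ml O2.
#' @export
o2_content <- function(hb, sat, volume) {
  stopifnot(hb >= 0, all(sat >= 0), all(volume >= 0))
  o2_k * hb * sat * volume
}

#' Upwind convective oxygen transport over a fixed flow field
#'
#' Advances per-compartment saturations over `n_steps` explicit steps:
#' each compartment exports oxygen at its own (homogeneous) saturation and
#' receives it at the donor's saturation, so total content is conserved
#' exactly.  This is the same scheme the solver applies after every
#' hemodynamic step; it is exported so it can be checked against
#' closed-form solutions on small networks.
#'
#' @param volumes Compartment volumes, ml.
#' @param saturations Initial saturations, percent.
#' @param edges Data frame with integer columns `from`, `to` (1-based
#'   compartment indices) and `q` (flow, ml/s, signed).
#' @param hb Hemoglobin, g/l.
#' @param dt Time step, s.
#' @param n_steps Number of steps.
#' @return Saturations after `n_steps * dt` seconds.
#' @export
o2_advect <- function(volumes, saturations, edges, hb, dt, n_steps = 1L) {
  stopifnot(length(volumes) == length(saturations),
            all(c("from", "to", "q") %in% names(edges)))
  cpp_o2_advect(volumes, saturations, as.integer(edges$from) - 1L,
                as.integer(edges$to) - 1L, edges$q, hb, dt,
                as.integer(n_steps))
}

#' Pulmonary capillary oxygenation with shunt
#'
#' Flow-weighted mixing of oxygenated and shunted blood: the non-shunted
#' fraction leaves the gas-exchanging capillaries at `sat_cap` (99.4 % by
#' default, corresponding to a normal alveolar pO2), the shunt fraction
#' keeps the incoming mixed-venous saturation.
#'
#' @param sat_in Incoming (pulmonary arterial) saturation, percent.
#' @param shunt_fraction Pulmonary shunt fraction in `[0, 1]`.
#' @param sat_cap End-capillary saturation, percent.
#' @return Mixed saturation entering the pulmonary veins, percent.
#' @examples
#' pulmonary_oxygenation(68.3, 0.1)  # about the normal arterial 96.3 %
#' @export
pulmonary_oxygenation <- function(sat_in, shunt_fraction, sat_cap = 99.4) {
  if (shunt_fraction < 0 || shunt_fraction > 1)
    stop("pulmonary_oxygenation: shunt_fraction must be in [0, 1]")
  cpp_pulmonary_mix(sat_in, shunt_fraction, sat_cap)
}

#' Myocardial oxygen consumption from the pressure-volume area
#'
#' Beat-level myocardial oxygen demand after the pressure-volume-area
#' concept: `VO2_beat = (a * PVA + b * Ees + c) * mass / 100` ml O2 per
#' beat per ventricle, with `PVA` the stroke work plus the end-systolic
#' potential energy `0.5 * Pes * (Ves - V0)`.  Multiplied by heart rate to
#' give ml O2/min; the demand is extracted from coronary microvascular
#' blood during the simulation.
#'
#' @param sw Stroke work (pressure-volume loop area), mmHg ml.
#' @param pes,ves End-systolic pressure (mmHg) and volume (ml).
#' @param v0 ESPVR volume intercept, ml.
#' @param ees End-systolic elastance, mmHg/ml.
#' @param mass Ventricular mass, g.
#' @param hr Heart rate, 1/min.
#' @param coef Coefficients `c(a, b, c)` per 100 g of myocardium:
#'   ml O2/(mmHg ml), ml O2/(mmHg/ml), ml O2 (literature defaults).
#' @return Oxygen consumption, ml O2/min.
#' @export
myocardial_vo2 <- function(sw, pes, ves, v0, ees, mass, hr,
                           coef = c(1.8e-05, 0.0024, 0.014)) {
  pva <- max(sw, 0) + max(0.5 * pes * (ves - v0), 0)
  vo2_beat <- (coef[1] * pva + coef[2] * ees + coef[3]) * mass / 100
  vo2_beat * hr
}

#' Systemic oxygen consumption step
#'
#' Removes oxygen from the systemic capillary compartments at the
#' configured rate, distributed in proportion to the supplied weights
#' (compartment flows during simulation); saturations are floored at zero
#' with a warning.
#'
#' @param saturations Capillary saturations, percent.
#' @param volumes Capillary volumes, ml.
#' @param hb Hemoglobin, g/l.
#' @param vo2 Systemic oxygen consumption, ml O2/min.
#' @param dt Time step, s.
#' @param weights Distribution weights (normalised internally).
#' @return Updated saturations, percent.
#' @export
consume_systemic <- function(saturations, volumes, hb, vo2, dt,
                             weights = rep(1, length(saturations))) {
  stopifnot(vo2 >= 0, length(saturations) == length(volumes))
  w <- weights / sum(weights)
  content <- o2_content(hb, saturations, volumes)
  content <- content - vo2 / 60 * dt * w
  if (any(content < 0)) {
    warning("consume_systemic: oxygen content exhausted; saturation floored at 0")
    content[content < 0] <- 0
  }
  content / (o2_k * hb * volumes)
}
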