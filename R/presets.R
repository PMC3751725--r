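# Baseline preset: a healthy resting 70 kg adult (blood volume 5600 ml,
# heart rate 72/min).  Named conduit arteries carry anatomical dimensions
# (after the cited aortic anatomy literature); lumped peripheral beds are
# reconstructed from design targets (resistance, contained volume,
# compliance at the normal mean pressure) by inverting the Poiseuille /
# volume / elastance relations at an assumed single-vessel radius.  Each
# segment records its provenance ("anatomical" vs "calibrated").

#' Vascular segment constructors
#'
#' `cv_segment()` builds a segment from explicit geometry.
#' `cv_segment_targets()` reconstructs the geometry of a lumped bed from
#' design targets -- resistance `R` (mmHg s/ml), contained volume `V`
#' (ml) and compliance `C` (ml/mmHg) at the normal mean pressure -- by
#' inverting the Poiseuille/volume/elastance relations at an assumed
#' single-vessel radius (`V * R = 8 eta l^2 / r0^2`).
#'
#' @param r0,radius0 Single-vessel radius, cm.
#' @param R,V,C Design targets (see above).
#' @param length,thickness Vessel length and wall thickness, cm.
#' @param count Number of parallel vessels.
#' @param p0 Normal mean pressure, mmHg.
#' @param group External pressure group.
#' @param eta Blood viscosity, mmHg s.
#' @param y_inc Young's modulus used to size the wall, mmHg.
#' @param ... Further segment fields (`init_sat`, `compress_chamber`,
#'   `compress_k`, `lambda`, `linear`, `init_volume`, `provenance`).
#' @return A segment parameter list.
#' @export
cv_segment_targets <- function(r0, R, V, C, p0,
                               group = "extrathoracic",
                               eta = 0.00024, y_inc = 3000, ...) {
  seg_lumped(r0, R, V, C, p0, group, eta, y_inc, ...)
}

#' @rdname cv_segment_targets
#' @export
cv_segment <- function(length, radius0, thickness, count, p0,
                       group = "extrathoracic", ...) {
  seg(length = length, radius0 = radius0, thickness = thickness,
      count = count, p0 = p0, group = group, provenance = "user", ...)
}

# Solve (l, n, h) of a lumped bed from targets R (mmHg s/ml), V (ml),
# C (ml/mmHg) at assumed radius r0:  V * R = 8 eta l^2 / r0^2.
seg_lumped <- function(r0, R, V, C, p0, group, eta = 0.00024,
                       y_inc = 3000, ...) {
  l <- sqrt(V * R * r0^2 / (8 * eta))
  n <- V / (pi * r0^2 * l)
  h <- 2 * pi * r0^3 * l * n / (C * y_inc)
  seg(length = l, radius0 = r0, thickness = h, count = n, p0 = p0,
      group = group, provenance = "calibrated", ...)
}

# Named vessel with anatomical length/radius/count; wall thickness set
# from the compliance target at the baseline Young's modulus.
seg_anatomic <- function(l, r0, n, C, p0, group, y_inc = 3000, ...) {
  h <- 2 * pi * r0^3 * l * n / (C * y_inc)
  seg(length = l, radius0 = r0, thickness = h, count = n, p0 = p0,
      group = group, provenance = "anatomical", ...)
}

seg <- function(length, radius0, thickness, count, p0, group,
                provenance, init_sat = 96.2, compress_chamber = NA,
                compress_k = 0, lambda = NA, linear = FALSE,
                init_volume = NA) {
  if (is.na(init_volume))
    init_volume <- pi * radius0^2 * length * count
  list(length = length, radius0 = radius0, thickness = thickness,
       count = count, p0 = p0, external_group = group,
       lambda = lambda, compress_chamber = compress_chamber,
       compress_k = compress_k, linear_pv = linear,
       init_volume = init_volume, init_sat = init_sat,
       provenance = provenance)
}

chamber <- function(e_max, e_min, v0, v0_dia, phi_dia, alpha1, alpha2,
                    n1 = 1.32, n2 = 27.4, onset = 0, r_wall = 0.0005,
                    r_outflow = 0.001, starling_v_th = 20,
                    starling_width = 29, starling_depth = 0.5,
                    mass = 100, init_volume = 100, init_sat = 96.2) {
  list(e_max = e_max, e_min = e_min, v0 = v0, v0_dia = v0_dia,
       phi_dia = phi_dia, alpha1 = alpha1, alpha2 = alpha2, n1 = n1,
       n2 = n2, onset = onset, r_wall = r_wall, r_outflow = r_outflow,
       starling_v_th = starling_v_th, starling_width = starling_width,
       starling_depth = starling_depth, mass = mass,
       init_volume = init_volume, init_sat = init_sat)
}

#' Built-in parameter presets
#'
#' `cv_preset("normal")` returns the calibrated baseline parameter set of
#' a healthy resting adult.  Pathology and maneuver presets are expressed
#' as scenario patch files applied on top of the baseline; see
#' [cv_scenarios()] and [run_scenario()].
#'
#' @param name Preset name; currently only `"normal"` is a full parameter
#'   set.
#' @return A `cvloop_params` object.
#' @export
cv_preset <- function(name = "normal") {
  if (!identical(name, "normal"))
    stop("unknown preset '", name, "'; full parameter sets: 'normal' ",
         "(pathologies are scenario patches, see cv_scenarios())")

  global <- list(
    blood_volume = 5600, blood_viscosity = 0.00024, blood_density = 1.060,
    heart_rate = 72, dt = 0.00025, hb = 140, vo2_systemic = 250,
    pulm_cap_sat = 99.4, pulm_shunt_fraction = 0.10, young_modulus = 3000,
    damping_lambda = 0.5, intrathoracic_pressure = 0, hr_alpha_ref = 72)

  chambers <- list(
    lv = chamber(2.8, 0.05, 0, 4, 145, 0.29, 0.48, n1 = 5.0, onset = 0.16,
                 r_wall = 0.0015, r_outflow = 0.003, mass = 150,
                 starling_v_th = 100, starling_width = 70,
                 starling_depth = 0.5,
                 init_volume = 125, init_sat = 96.2),
    rv = chamber(0.48, 0.036, 0, -10, 200, 0.29, 0.48, n1 = 5.0, onset = 0.16,
                 r_wall = 0.0008, r_outflow = 0.0015, mass = 60,
                 starling_v_th = 100, starling_width = 70,
                 starling_depth = 0.5,
                 init_volume = 125, init_sat = 68.3),
    la = chamber(0.10, 0.060, 5, 30, 30, 0.070, 0.125, onset = 0,
                 r_wall = 0.0005, r_outflow = 0.0005,
                 starling_v_th = 90, starling_width = 30,
                 starling_depth = 0.3, mass = 25, init_volume = 60,
                 init_sat = 96.2),
    ra = chamber(0.10, 0.045, 5, 25, 35, 0.070, 0.125, onset = 0,
                 r_wall = 0.0005, r_outflow = 0.0005,
                 starling_v_th = 90, starling_width = 30,
                 starling_depth = 0.3, mass = 20, init_volume = 60,
                 init_sat = 68.3))

  valves <- list(
    mitral    = list(a_min = 0, a_max = 7.0, k_open = 30, k_close = 30),
    aortic    = list(a_min = 0, a_max = 5.0, k_open = 20, k_close = 30),
    tricuspid = list(a_min = 0, a_max = 8.0, k_open = 30, k_close = 30),
    pulmonic  = list(a_min = 0, a_max = 5.0, k_open = 20, k_close = 30))

  ex <- "extrathoracic"; th <- "intrathoracic"; pe <- "pericardial"
  segments <- list(
    aortic_root = seg_anatomic(3.5, 1.45, 1, C = 0.11, p0 = 79, group = th),
    asc_aorta   = seg_anatomic(5.0, 1.40, 1, C = 0.19, p0 = 79, group = th),
    prox_arch   = seg_anatomic(3.0, 1.25, 1, C = 0.09, p0 = 78.5, group = th),
    dist_arch   = seg_anatomic(4.0, 1.15, 1, C = 0.095, p0 = 78, group = th),
    desc_aorta  = seg_anatomic(25.0, 0.90, 1, C = 0.34, p0 = 77, group = th),
    periph_art  = seg_lumped(0.25, R = 0.030, V = 235, C = 0.70, p0 = 75,
                             group = ex),
    sys_arteriolae = seg_lumped(0.005, R = 0.85, V = 8, C = 0.05, p0 = 45,
                                group = ex),
    sys_cap     = seg_lumped(4e-04, R = 0.24, V = 215, C = 0.30, p0 = 18,
                             group = ex, init_sat = 82),
    sys_veins   = seg_lumped(0.02, R = 0.014, V = 3030, C = 45, p0 = 4.3,
                             group = ex, init_sat = 70),
    ivc         = seg_lumped(0.80, R = 0.006, V = 500, C = 15, p0 = 3.9,
                             group = th, init_sat = 70),
    r_carotid   = seg_anatomic(20.0, 0.40, 2, C = 0.048, p0 = 76, group = ex),
    r_car_arteriolae = seg_lumped(0.004, R = 6.6, V = 1.2, C = 0.02,
                                  p0 = 40, group = ex),
    r_car_capvein = seg_lumped(0.010, R = 0.90, V = 150, C = 4, p0 = 6,
                               group = ex, init_sat = 78),
    l_carotid   = seg_anatomic(20.0, 0.40, 2, C = 0.048, p0 = 76, group = ex),
    l_car_arteriolae = seg_lumped(0.004, R = 6.6, V = 1.2, C = 0.02,
                                  p0 = 40, group = ex),
    l_car_capvein = seg_lumped(0.010, R = 0.90, V = 150, C = 4, p0 = 6,
                               group = ex, init_sat = 78),
    svc         = seg_lumped(0.70, R = 0.006, V = 180, C = 8, p0 = 3.8,
                             group = th, init_sat = 72),
    pulm_trunk  = seg_anatomic(7.0, 1.30, 3, C = 1.8, p0 = 11, group = th,
                               init_sat = 68.3),
    pu_arteriolae = seg_lumped(0.006, R = 0.045, V = 10, C = 0.12,
                               p0 = 9.5, group = th, init_sat = 68.3),
    pu_cap      = seg_lumped(5e-04, R = 0.018, V = 123, C = 2.5, p0 = 6.1,
                             group = th, init_sat = 96.4),
    pu_smallveins = seg_lumped(0.015, R = 0.006, V = 150, C = 4, p0 = 4.7,
                               group = th, init_sat = 96.3),
    pu_veins    = seg_lumped(0.60, R = 0.003, V = 180, C = 3, p0 = 4.3,
                             group = th, init_sat = 96.3),
    l_cor_epi   = seg_anatomic(10.0, 0.20, 1, C = 0.010, p0 = 75,
                               group = pe),
    l_cor_micro = seg_lumped(0.003, R = 21, V = 8, C = 0.05, p0 = 35,
                             group = pe, init_sat = 35,
                             compress_chamber = "lv", compress_k = 0.4),
    r_cor_epi   = seg_anatomic(8.0, 0.15, 1, C = 0.005, p0 = 75,
                               group = pe),
    r_cor_micro = seg_lumped(0.003, R = 118, V = 4, C = 0.02, p0 = 35,
                             group = pe, init_sat = 35,
                             compress_chamber = "rv", compress_k = 0.4))

  params <- list(
    global = global,
    chambers = chambers,
    valves = valves,
    septum = list(esv0 = 12, esa = 1.5),
    pericardium = list(p_min = -2, p_scale = 0.5, v_pc0 = 720, phi = 50,
                       myocardial_volume = 380),
    segments = segments,
    topology = default_edges(),
    shunts = list(asd = list(area = 0), vsd = list(area = 0),
                  pda = list(area = 0), gorlin_c = 1, g = 980),
    oxygen = list(pva_a = 1.8e-05, pva_b = 0.0024, pva_c = 0.014,
                  pulm_cap = "pu_cap",
                  sys_sinks = c("sys_cap", "r_car_capvein",
                                "l_car_capvein"),
                  myo_sink_left = "l_cor_micro",
                  myo_sink_right = "r_cor_micro"),
    baroreflex = list(enabled = FALSE, setpoint = 79, tau = 2,
                      gain_hr = 2, gain_emax = 1.5, gain_res = 2,
                      mult_min = 0.5, mult_max = 2, sense = "asc_aorta"),
    ecg = list(w_lv = 1, w_rv = 0.3, w_la = 0.12, w_ra = 0.1,
               delay = 0.06),
    solver = list(newton_tol = 1e-09, newton_maxit = 20,
                  jac_interval = 25, record_dt = 0.001,
                  osc_comp = "asc_aorta"),
    af = list(enabled = FALSE, rr_jitter = 0.25, seed = 1))
  class(params) <- "cvloop_params"
  cv_validate(params)
  params
}

#' @export
print.cvloop_params <- function(x, ...) {
  cat("cvloop parameter set\n")
  cat(sprintf("  blood volume %g ml, HR %g/min, Hb %g g/l, dt %g ms\n",
              x$global$blood_volume, x$global$heart_rate, x$global$hb,
              x$global$dt * 1000))
  cat(sprintf("  %d vascular segments, %d branches (%d with flow states)\n",
              length(x$segments), nrow(x$topology),
              sum(x$topology$stateful)))
  invisible(x)
}
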