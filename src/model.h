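// Scalar model primitives shared by the exported unit operations and the
// time-stepping engine.  Unit system: pressure mmHg, volume ml (= cm^3),
// flow ml/s, time s, geometry cm.  CGS mechanical constants (density in
// g/cm^3, g in cm/s^2) are converted with 1 mmHg = 1333.22 g cm^-1 s^-2.
#ifndef CVLOOP_MODEL_H
#define CVLOOP_MODEL_H

#include <cmath>
#include <algorithm>

namespace cvl {

constexpr double MMHG_CGS = 1333.22;   // dyn/cm^2 per mmHg
constexpr double O2_K = 0.0000136;     // ml O2 per (g/l Hb * % sat * ml blood)
constexpr double PI = 3.14159265358979323846;

// ---- cardiac chambers -------------------------------------------------

// Raw (unnormalised) Double-Hill activation on the phase axis phi in [0,1):
// product of a rising Hill sigmoid (exponent n1, half-width a1) and a
// falling one (exponent n2, half-width a2), a1/a2 expressed as fractions
// of the cycle.
inline double dh_raw(double phi, double a1, double a2, double n1, double n2) {
    if (phi <= 0.0) return 0.0;
    double u1 = std::pow(phi / a1, n1);
    double u2 = std::pow(phi / a2, n2);
    return (u1 / (1.0 + u1)) / (1.0 + u2);
}

// Phase of the single interior maximum, by dense scan plus ternary
// refinement (the function is unimodal on (0,1)).
inline double dh_peak_phase(double a1, double a2, double n1, double n2) {
    const int N = 4096;
    double best = 0.0, bestv = -1.0;
    for (int i = 1; i < N; ++i) {
        double phi = (double)i / N;
        double v = dh_raw(phi, a1, a2, n1, n2);
        if (v > bestv) { bestv = v; best = phi; }
    }
    double lo = std::max(best - 1.0 / N, 1e-12);
    double hi = std::min(best + 1.0 / N, 1.0 - 1e-12);
    for (int it = 0; it < 200; ++it) {
        double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
        if (dh_raw(m1, a1, a2, n1, n2) < dh_raw(m2, a1, a2, n1, n2)) lo = m1;
        else hi = m2;
    }
    return 0.5 * (lo + hi);
}

inline double dh_norm_const(double a1, double a2, double n1, double n2) {
    return dh_raw(dh_peak_phase(a1, a2, n1, n2), a1, a2, n1, n2);
}

// Starling contractility roll-off: multiplier on e_max, exactly 1 at or
// below the threshold volume, smooth (C1) monotone decrease above it,
// saturating at 1 - depth.
inline double starling_mult(double v, double v_th, double width, double depth) {
    if (v <= v_th || depth <= 0.0) return 1.0;
    double z = (v - v_th) / width;
    return 1.0 - depth * std::tanh(z * z);
}

// Nonlinear end-diastolic pressure-volume relation:
// p = e_min * phi * (exp((v - v0)/phi) - 1); slope e_min at v = v0.
inline double passive_pressure(double v, double e_min, double v0, double phi) {
    return e_min * phi * std::expm1((v - v0) / phi);
}

inline double passive_slope(double v, double e_min, double v0, double phi) {
    return e_min * std::exp((v - v0) / phi);
}

// Pericardial pressure as exponential in contained volume; minimum may be
// negative.
inline double pericardial_pressure(double v, double p_min, double p_scale,
                                   double v_pc0, double phi) {
    return p_min + p_scale * std::exp((v - v_pc0) / phi);
}

// ---- valves and shunts ------------------------------------------------

// Valve blood inertance L = rho * 2 / (pi * r), with the inflow length set
// to the instantaneous valve diameter; converted from g/cm^4 to
// mmHg s^2/ml.
inline double valve_inertance(double a_eff, double rho) {
    double r = std::sqrt(a_eff / PI);
    return (2.0 * rho / (PI * r)) / MMHG_CGS;
}

// Bernoulli orifice pressure drop rho/(2 A^2) q|q|, converted to mmHg.
inline double bernoulli_gradient(double q, double a_eff, double rho) {
    return (rho / (2.0 * a_eff * a_eff)) * q * std::fabs(q) / MMHG_CGS;
}

// Gorlin orifice flow Q = C A sqrt(2 g dP) = 44.3 A sqrt(dP); signed,
// bidirectional, dP in mmHg, A in cm^2, Q in ml/s.
inline double gorlin_flow(double area, double dp, double gorlin_c, double g) {
    double coef = gorlin_c * std::sqrt(2.0 * g);
    double s = (dp >= 0.0) ? 1.0 : -1.0;
    return coef * area * std::sqrt(std::fabs(dp)) * s;
}

// Pressure-difference driven first-order valve opening dynamics.
inline double zeta_rate(double zeta, double dp, double k_open, double k_close) {
    if (dp > 0.0) return k_open * dp * (1.0 - zeta);
    if (dp < 0.0) return k_close * dp * zeta;
    return 0.0;
}

// ---- vascular segments ------------------------------------------------

// Poiseuille resistance of n parallel vessels, mmHg s/ml (eta in mmHg s).
inline double base_resistance(double eta, double l, double r0, double n) {
    return 8.0 * eta * l / (PI * r0 * r0 * r0 * r0 * n);
}

// Blood inertance of n parallel vessels, converted CGS -> mmHg s^2/ml.
inline double base_inertance(double rho, double l, double r0, double n) {
    return (rho * l / (PI * r0 * r0 * n)) / MMHG_CGS;
}

// Volume elastance from incremental Young's modulus (mmHg), mmHg/ml.
inline double base_elastance(double y_inc, double h, double r0, double l,
                             double n) {
    return y_inc * h / (2.0 * PI * r0 * r0 * r0 * l * n);
}

// Anchored exponential transmural pressure-volume relation:
// p(v) = p0 exp((e0/p0)(v - v_ref)), so p(v_ref) = p0 and dp/dv = e0 there.
// linear = true swaps in the linearised relation (used by the Windkessel
// oracle fixtures).
inline double transmural_pressure(double v, double v_ref, double p0,
                                  double e0, bool linear = false) {
    if (linear) return p0 + e0 * (v - v_ref);
    double x = (e0 / p0) * (v - v_ref);
    // linear continuation far outside the physiological range keeps
    // Newton iterates finite (never reached by accepted states)
    if (x > 20.0) return p0 * std::exp(20.0) * (1.0 + (x - 20.0));
    return p0 * std::exp(x);
}

// Instantaneous properties at volume v: radius scales as sqrt(v/v_ref)
// with constant length and wall thickness, so R ~ r^-4, I ~ r^-2, E ~ r^-3.
// volumes are floored at 2 % of the reference inside the property
// evaluations so that transient Newton iterates cannot overflow; accepted
// solver states are separately required to stay positive
inline double seg_resistance_now(double r0_base, double v, double v_ref) {
    double x = v_ref / std::max(v, 0.02 * v_ref);
    return r0_base * x * x;
}
inline double seg_inertance_now(double i0_base, double v, double v_ref) {
    return i0_base * (v_ref / std::max(v, 0.02 * v_ref));
}
inline double seg_elastance_now(double e0_base, double v, double v_ref) {
    return e0_base * std::pow(std::max(v, 0.02 * v_ref) / v_ref, -1.5);
}

// Viscoelastic wall damping in series with the compliance branch,
// Omega = lambda * sqrt(I * E)  (the characteristic-impedance form).
inline double wall_damping(double i_now, double e_now, double lambda) {
    return lambda * std::sqrt(i_now * e_now);
}

// ---- oxygen ------------------------------------------------------------

// Blood O2 content, ml O2 (Hb g/l, sat percent, volume ml).
inline double o2_content(double hb, double sat, double volume) {
    return O2_K * hb * sat * volume;
}

// Flow-weighted pulmonary-capillary mixing: the non-shunted fraction is
// oxygenated to sat_cap, the shunt fraction keeps the incoming saturation.
inline double pulmonary_mix(double sat_in, double shunt_fraction,
                            double sat_cap) {
    return (1.0 - shunt_fraction) * sat_cap + shunt_fraction * sat_in;
}

} // namespace cvl

#endif
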