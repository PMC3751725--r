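// Exported unit operations.  These are thin wrappers around the scalar
// primitives in model.h, which are the same functions used by the
// time-stepping engine, so the tested formulas and the running model
// cannot drift apart.
#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// [[Rcpp::export(name = "cpp_dh_activation")]]
NumericVector cpp_dh_activation(NumericVector phi, double a1, double a2,
                                double n1, double n2) {
    if (a1 <= 0.0 || a2 <= 0.0)
        stop("double_hill_activation: alpha1 and alpha2 must be positive");
    double norm = cvl::dh_norm_const(a1, a2, n1, n2);
    NumericVector out(phi.size());
    for (R_xlen_t i = 0; i < phi.size(); ++i)
        out[i] = cvl::dh_raw(phi[i], a1, a2, n1, n2) / norm;
    return out;
}

// [[Rcpp::export(name = "cpp_dh_peak_phase")]]
double cpp_dh_peak_phase(double a1, double a2, double n1, double n2) {
    return cvl::dh_peak_phase(a1, a2, n1, n2);
}

// [[Rcpp::export(name = "cpp_starling_mult")]]
NumericVector cpp_starling_mult(NumericVector v, double v_th, double width,
                                double depth) {
    NumericVector out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i)
        out[i] = cvl::starling_mult(v[i], v_th, width, depth);
    return out;
}

// [[Rcpp::export(name = "cpp_passive_pressure")]]
NumericVector cpp_passive_pressure(NumericVector v, double e_min, double v0,
                                   double phi) {
    NumericVector out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i)
        out[i] = cvl::passive_pressure(v[i], e_min, v0, phi);
    return out;
}

// [[Rcpp::export(name = "cpp_pericardial_pressure")]]
NumericVector cpp_pericardial_pressure(NumericVector v, double p_min,
                                       double p_scale, double v_pc0,
                                       double phi) {
    NumericVector out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i)
        out[i] = cvl::pericardial_pressure(v[i], p_min, p_scale, v_pc0, phi);
    return out;
}

// [[Rcpp::export(name = "cpp_valve_inertance")]]
double cpp_valve_inertance(double a_eff, double rho) {
    return cvl::valve_inertance(a_eff, rho);
}

// [[Rcpp::export(name = "cpp_valve_gradient")]]
double cpp_valve_gradient(double q, double dq_dt, double a_eff, double rho) {
    return cvl::bernoulli_gradient(q, a_eff, rho) +
           cvl::valve_inertance(a_eff, rho) * dq_dt;
}

// [[Rcpp::export(name = "cpp_gorlin_flow")]]
NumericVector cpp_gorlin_flow(double area, NumericVector dp, double gorlin_c,
                              double g) {
    NumericVector out(dp.size());
    for (R_xlen_t i = 0; i < dp.size(); ++i)
        out[i] = cvl::gorlin_flow(area, dp[i], gorlin_c, g);
    return out;
}

// [[Rcpp::export(name = "cpp_zeta_rate")]]
double cpp_zeta_rate(double zeta, double dp, double k_open, double k_close) {
    return cvl::zeta_rate(zeta, dp, k_open, k_close);
}

// [[Rcpp::export(name = "cpp_base_resistance")]]
double cpp_base_resistance(double eta, double l, double r0, double n) {
    return cvl::base_resistance(eta, l, r0, n);
}

// [[Rcpp::export(name = "cpp_base_inertance")]]
double cpp_base_inertance(double rho, double l, double r0, double n) {
    return cvl::base_inertance(rho, l, r0, n);
}

// [[Rcpp::export(name = "cpp_base_elastance")]]
double cpp_base_elastance(double y_inc, double h, double r0, double l,
                          double n) {
    return cvl::base_elastance(y_inc, h, r0, l, n);
}

// [[Rcpp::export(name = "cpp_transmural_pressure")]]
NumericVector cpp_transmural_pressure(NumericVector v, double v_ref,
                                      double p0, double e0, bool linear) {
    NumericVector out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i)
        out[i] = cvl::transmural_pressure(v[i], v_ref, p0, e0, linear);
    return out;
}

// [[Rcpp::export(name = "cpp_segment_now")]]
NumericVector cpp_segment_now(double v, double v_ref, double r0_base,
                              double i0_base, double e0_base, double lambda) {
    double r = cvl::seg_resistance_now(r0_base, v, v_ref);
    double i = cvl::seg_inertance_now(i0_base, v, v_ref);
    double e = cvl::seg_elastance_now(e0_base, v, v_ref);
    double w = cvl::wall_damping(i, e, lambda);
    return NumericVector::create(_["r_now"] = r, _["i_now"] = i,
                                 _["e_now"] = e, _["omega_now"] = w);
}

// [[Rcpp::export(name = "cpp_wall_damping")]]
double cpp_wall_damping(double i_now, double e_now, double lambda) {
    return cvl::wall_damping(i_now, e_now, lambda);
}

// [[Rcpp::export(name = "cpp_o2_content")]]
double cpp_o2_content(double hb, double sat, double volume) {
    return cvl::o2_content(hb, sat, volume);
}

// [[Rcpp::export(name = "cpp_pulmonary_mix")]]
double cpp_pulmonary_mix(double sat_in, double shunt_fraction,
                         double sat_cap) {
    return cvl::pulmonary_mix(sat_in, shunt_fraction, sat_cap);
}
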