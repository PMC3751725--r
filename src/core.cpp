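// Time-stepping engine: assembles the closed-loop network RHS from the
// packed parameter set, advances it with implicit Euler (chord-Newton with
// finite-difference Jacobian, LU reuse, halved sub-steps on failure),
// carries the oxygen sub-step and the baroreflex filter, and records
// decimated traces plus per-beat energetics.
#include <RcppArmadillo.h>
#include "model.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Pack {
    // global
    double dt, hb, vo2_sys, sat_cap, shunt_frac, p_thorax, hr, hr_alpha_ref,
        rho, blood_volume;
    // chambers (always 4: LV, RV, LA, RA)
    double emax[4], emin[4], v0[4], v0d[4], phid[4], a1[4], a2[4], n1[4],
        n2[4], onset[4], rwall[4], routflow[4], st_vth[4], st_w[4],
        st_depth[4], mass[4];
    // septum / pericardium
    double esv0, esa;
    double pc_pmin, pc_pscale, pc_v0, pc_phi, pc_vmyo;
    // valves (4): mitral, aortic, tricuspid, pulmonic
    int v_up[4], v_dn[4];
    double v_amin[4], v_amax[4], v_ko[4], v_kc[4];
    // segments
    int nseg;
    std::vector<double> s_vref, s_p0, s_e0, s_r0, s_i0, s_lam;
    std::vector<int> s_group, s_compch, s_linear;
    std::vector<double> s_compk;
    // edges
    int nq, nalg;
    std::vector<int> e_from, e_to;     // stateful
    std::vector<int> a_from, a_to;     // algebraic (resistive)
    // shunts
    int nsh;
    std::vector<int> sh_c1, sh_c2;
    std::vector<double> sh_area;
    double gorlin_c, grav;
    // baroreflex
    int baro_on, baro_sense;
    double baro_setp, baro_tau, baro_ghr, baro_gem, baro_gres, baro_mmin,
        baro_mmax;
    std::vector<int> baro_res_segs;
    // oxygen
    double pva_a, pva_b, pva_c;
    int o2_pulm_cap;
    std::vector<int> o2_sys_sinks;
    int o2_myo_sink[2];   // compartment extracting left / right myocardial O2
    // ecg
    double ecg_w[4], ecg_delay;
    // numerics
    double tol;
    int maxit, jacint;
    // atrial fibrillation RR randomiser
    int af_on;
    double af_jitter;
    // monitoring
    int osc_comp;

    int ncomp() const { return 4 + nseg; }
    int nx() const { return ncomp() + nq + 8; }
};

double getd(const List& L, const char* n) { return as<double>(L[n]); }
int geti(const List& L, const char* n) { return as<int>(L[n]); }

void getd4(const List& L, const char* n, double* out) {
    NumericVector v = L[n];
    for (int i = 0; i < 4; ++i) out[i] = v[i];
}
void geti4(const List& L, const char* n, int* out) {
    IntegerVector v = L[n];
    for (int i = 0; i < 4; ++i) out[i] = v[i];
}

Pack parse_pack(const List& L) {
    Pack P;
    List g = L["global"];
    P.dt = getd(g, "dt"); P.hb = getd(g, "hb");
    P.vo2_sys = getd(g, "vo2_systemic"); P.sat_cap = getd(g, "pulm_cap_sat");
    P.shunt_frac = getd(g, "pulm_shunt_fraction");
    P.p_thorax = getd(g, "intrathoracic_pressure");
    P.hr = getd(g, "heart_rate"); P.hr_alpha_ref = getd(g, "hr_alpha_ref");
    P.rho = getd(g, "blood_density");
    P.blood_volume = getd(g, "blood_volume");

    List ch = L["chambers"];
    getd4(ch, "e_max", P.emax); getd4(ch, "e_min", P.emin);
    getd4(ch, "v0", P.v0); getd4(ch, "v0_dia", P.v0d);
    getd4(ch, "phi_dia", P.phid);
    getd4(ch, "alpha1", P.a1); getd4(ch, "alpha2", P.a2);
    getd4(ch, "n1", P.n1); getd4(ch, "n2", P.n2);
    getd4(ch, "onset", P.onset);
    getd4(ch, "r_wall", P.rwall); getd4(ch, "r_outflow", P.routflow);
    getd4(ch, "starling_v_th", P.st_vth); getd4(ch, "starling_width", P.st_w);
    getd4(ch, "starling_depth", P.st_depth); getd4(ch, "mass", P.mass);

    List sp = L["septum"];
    P.esv0 = getd(sp, "esv0"); P.esa = getd(sp, "esa");
    List pc = L["pericardium"];
    P.pc_pmin = getd(pc, "p_min"); P.pc_pscale = getd(pc, "p_scale");
    P.pc_v0 = getd(pc, "v_pc0"); P.pc_phi = getd(pc, "phi");
    P.pc_vmyo = getd(pc, "myocardial_volume");

    List va = L["valves"];
    geti4(va, "up", P.v_up); geti4(va, "down", P.v_dn);
    getd4(va, "a_min", P.v_amin); getd4(va, "a_max", P.v_amax);
    getd4(va, "k_open", P.v_ko); getd4(va, "k_close", P.v_kc);

    List sg = L["segments"];
    NumericVector vref = sg["v_ref"];
    P.nseg = vref.size();
    P.s_vref = as<std::vector<double>>(sg["v_ref"]);
    P.s_p0 = as<std::vector<double>>(sg["p0"]);
    P.s_e0 = as<std::vector<double>>(sg["e0"]);
    P.s_r0 = as<std::vector<double>>(sg["r0"]);
    P.s_i0 = as<std::vector<double>>(sg["i0"]);
    P.s_lam = as<std::vector<double>>(sg["lambda"]);
    P.s_group = as<std::vector<int>>(sg["group"]);
    P.s_compch = as<std::vector<int>>(sg["compress_chamber"]);
    P.s_compk = as<std::vector<double>>(sg["compress_k"]);
    P.s_linear = as<std::vector<int>>(sg["linear"]);

    List ed = L["edges"];
    P.e_from = as<std::vector<int>>(ed["from"]);
    P.e_to = as<std::vector<int>>(ed["to"]);
    P.nq = P.e_from.size();
    P.a_from = as<std::vector<int>>(ed["alg_from"]);
    P.a_to = as<std::vector<int>>(ed["alg_to"]);
    P.nalg = P.a_from.size();

    List sh = L["shunts"];
    P.sh_c1 = as<std::vector<int>>(sh["c1"]);
    P.sh_c2 = as<std::vector<int>>(sh["c2"]);
    P.sh_area = as<std::vector<double>>(sh["area"]);
    P.nsh = P.sh_area.size();
    P.gorlin_c = getd(sh, "gorlin_c"); P.grav = getd(sh, "g");

    List ba = L["baroreflex"];
    P.baro_on = geti(ba, "enabled"); P.baro_sense = geti(ba, "sense");
    P.baro_setp = getd(ba, "setpoint"); P.baro_tau = getd(ba, "tau");
    P.baro_ghr = getd(ba, "gain_hr"); P.baro_gem = getd(ba, "gain_emax");
    P.baro_gres = getd(ba, "gain_res");
    P.baro_mmin = getd(ba, "mult_min"); P.baro_mmax = getd(ba, "mult_max");
    P.baro_res_segs = as<std::vector<int>>(ba["res_segs"]);

    List ox = L["oxygen"];
    P.pva_a = getd(ox, "pva_a"); P.pva_b = getd(ox, "pva_b");
    P.pva_c = getd(ox, "pva_c");
    P.o2_pulm_cap = geti(ox, "pulm_cap");
    P.o2_sys_sinks = as<std::vector<int>>(ox["sys_sinks"]);
    IntegerVector ms = ox["myo_sinks"];
    P.o2_myo_sink[0] = ms[0]; P.o2_myo_sink[1] = ms[1];

    List ec = L["ecg"];
    getd4(ec, "w", P.ecg_w); P.ecg_delay = getd(ec, "delay");

    List nm = L["solver"];
    P.tol = getd(nm, "newton_tol"); P.maxit = geti(nm, "newton_maxit");
    P.jacint = geti(nm, "jac_interval");

    List af = L["af"];
    P.af_on = geti(af, "enabled"); P.af_jitter = getd(af, "rr_jitter");

    P.osc_comp = geti(L, "osc_comp");
    return P;
}

// Work buffers filled by the RHS evaluation.
struct Work {
    std::vector<double> act;     // 4
    std::vector<double> p_lum;   // ncomp
    std::vector<double> vdot;    // ncomp
    std::vector<double> q_alg;   // nalg
    std::vector<double> q_sh;    // nsh
    double p_peri;
    void init(const Pack& P) {
        act.assign(4, 0.0);
        p_lum.assign(P.ncomp(), 0.0);
        vdot.assign(P.ncomp(), 0.0);
        q_alg.assign(P.nalg, 0.0);
        q_sh.assign(P.nsh, 0.0);
        p_peri = 0.0;
    }
};

class Engine {
public:
    Pack P;
    // per-beat cached quantities
    double period;
    double a1e[4], a2e[4], normc[4], onsetf[4];
    double espf[2];               // ventricular end-systolic phase
    // baroreflex state
    double baro_f, m_hr, m_em, m_res;
    // AF RNG
    uint32_t rng;
    // myocardial oxygen rate (ml/min), left (LV+LA) and right (RV+RA)
    double vo2_myo[2];
    // beat accumulators
    double sw_acc[2], pes[2], ves[2], ees[2];
    bool es_done[2];
    double prev_plv[2], prev_v[2];
    double beat_t0;
    // oscillation counter (turning points of monitored pressure per beat)
    double osc_last, osc_extreme;
    int osc_dir, osc_count, osc_max;
    // diagnostics
    double o2_pulm_in, o2_sys_out, o2_myo_out;
    long newton_iters, jac_count, substeps, sat_clamps;
    std::vector<double> beat_rows;  // flattened rows, 16 cols
    int n_beat_rows;

    // chord-Newton data
    arma::mat Jinv;
    bool jac_valid;
    int steps_since_jac;
    double jac_dt;

    Work W;

    Engine(const Pack& p) : P(p) {
        W.init(P);
        jac_valid = false; steps_since_jac = 0; jac_dt = -1.0;
        o2_pulm_in = o2_sys_out = o2_myo_out = 0.0;
        newton_iters = jac_count = substeps = sat_clamps = 0;
        osc_dir = 0; osc_count = 0; osc_max = 0; osc_last = 0.0;
        osc_extreme = 0.0;
        n_beat_rows = 0;
        m_hr = m_em = m_res = 1.0;
        vo2_myo[0] = vo2_myo[1] = 0.0;
        for (int s = 0; s < 2; ++s) {
            sw_acc[s] = 0.0; pes[s] = 0.0; ves[s] = 0.0; ees[s] = 0.0;
            es_done[s] = false; prev_plv[s] = 0.0; prev_v[s] = 0.0;
        }
        beat_t0 = 0.0;
        baro_f = P.baro_setp; rng = 1u; period = 60.0 / P.hr;
        set_beat_params(period);
    }

    // recompute alpha scaling, normalisation constants, onset fractions for
    // a beat of the given period
    void set_beat_params(double per) {
        period = per;
        if (period > 1e06) {   // quiescent heart (heart rate zero)
            for (int c = 0; c < 4; ++c) {
                a1e[c] = P.a1[c]; a2e[c] = P.a2[c];
                normc[c] = 1.0; onsetf[c] = 0.0;
            }
            espf[0] = espf[1] = 0.5;
            return;
        }
        double hr_eff = 60.0 / period;
        double k = std::sqrt(hr_eff / P.hr_alpha_ref);
        for (int c = 0; c < 4; ++c) {
            a1e[c] = std::min(P.a1[c] * k, 0.95);
            a2e[c] = std::min(P.a2[c] * k, 0.98);
            normc[c] = cvl::dh_norm_const(a1e[c], a2e[c], P.n1[c], P.n2[c]);
            onsetf[c] = P.onset[c] / period;
        }
        for (int s = 0; s < 2; ++s)
            espf[s] = onsetf[s] +
                cvl::dh_peak_phase(a1e[s], a2e[s], P.n1[s], P.n2[s]);
    }

    double activation(int c, double phase) const {
        if (period > 1e06) return 0.0;
        double phi = phase - onsetf[c];
        phi -= std::floor(phi);
        // AF mode: atrial contraction suppressed
        if (P.af_on && c >= 2) return 0.0;
        return cvl::dh_raw(phi, a1e[c], a2e[c], P.n1[c], P.n2[c]) / normc[c];
    }

    double ecg(double phase) const {
        double out = 0.0;
        for (int c = 0; c < 4; ++c)
            out += P.ecg_w[c] * activation(c, phase + P.ecg_delay / period);
        return out;
    }

    double emax_eff(int c, double v) const {
        double m = (c < 2) ? m_em : 1.0;
        return P.emax[c] * m *
            cvl::starling_mult(v, P.st_vth[c], P.st_w[c], P.st_depth[c]);
    }

    // free (transmural, pre-viscous) chamber pressure at effective volume
    double chamber_free(int c, double v, double a) const {
        double pa = emax_eff(c, v) * (v - P.v0[c]);
        double pp = cvl::passive_pressure(v, P.emin[c], P.v0d[c], P.phid[c]);
        return a * pa + (1.0 - a) * pp;
    }

    double seg_Rnow(int i, double v) const {
        // fully linearised segments keep their base properties
        double r = P.s_linear[i]
            ? P.s_r0[i]
            : cvl::seg_resistance_now(P.s_r0[i], v, P.s_vref[i]);
        for (size_t k = 0; k < P.baro_res_segs.size(); ++k)
            if (P.baro_res_segs[k] == i) return r * m_res;
        return r;
    }

    double seg_Inow(int i, double v) const {
        return P.s_linear[i]
            ? P.s_i0[i]
            : cvl::seg_inertance_now(P.s_i0[i], v, P.s_vref[i]);
    }

    double seg_Enow(int i, double v) const {
        return P.s_linear[i]
            ? P.s_e0[i]
            : cvl::seg_elastance_now(P.s_e0[i], v, P.s_vref[i]);
    }

    // full network RHS; fills dx (length nx) and the work buffers
    void rhs(const double* x, double phase, double* dx) {
        const int nc = P.ncomp(), nq = P.nq;
        const double* vol = x;
        const double* qe = x + nc;
        const double* qv = x + nc + nq;
        const double* ze = x + nc + nq + 4;

        // 1. activations and free chamber pressures
        double pfree[4], elin[4];
        for (int c = 0; c < 4; ++c) {
            W.act[c] = activation(c, phase);
            pfree[c] = chamber_free(c, vol[c], W.act[c]);
            // local (tangent) elastance: activation-weighted blend of the
            // effective systolic elastance and the passive slope at the
            // current volume
            double epas = cvl::passive_slope(vol[c], P.emin[c], P.v0d[c],
                                             P.phid[c]);
            elin[c] = W.act[c] * emax_eff(c, vol[c]) +
                (1.0 - W.act[c]) * epas;
        }
        // 2. septal shifts (volume conserving: LV loses dv, RV gains dv)
        double esv = P.esv0 * elin[0];
        double dvv = (pfree[0] - pfree[1]) / (esv + elin[0] + elin[1]);
        double dva = (pfree[2] - pfree[3]) / (P.esa + elin[2] + elin[3]);
        double pfs[4];
        pfs[0] = chamber_free(0, vol[0] - dvv, W.act[0]);
        pfs[1] = chamber_free(1, vol[1] + dvv, W.act[1]);
        pfs[2] = chamber_free(2, vol[2] - dva, W.act[2]);
        pfs[3] = chamber_free(3, vol[3] + dva, W.act[3]);

        // 3. pericardial and external pressures, elastic luminal pressures
        double vheart = P.pc_vmyo;
        for (int c = 0; c < 4; ++c) vheart += vol[c];
        for (int i = 0; i < P.nseg; ++i)
            if (P.s_group[i] == 2) vheart += vol[4 + i];
        double pperi = cvl::pericardial_pressure(vheart, P.pc_pmin,
                                                 P.pc_pscale, P.pc_v0,
                                                 P.pc_phi);
        W.p_peri = pperi;
        double ext_heart = P.p_thorax + pperi;

        std::vector<double>& pel = W.p_lum;   // elastic first, viscous added later
        for (int c = 0; c < 4; ++c) pel[c] = pfs[c] + ext_heart;
        for (int i = 0; i < P.nseg; ++i) {
            double ext = 0.0;
            if (P.s_group[i] == 1) ext = P.p_thorax;
            else if (P.s_group[i] == 2) ext = ext_heart;
            if (P.s_compch[i] >= 0)
                ext += P.s_compk[i] * pel[P.s_compch[i]];
            pel[4 + i] = cvl::transmural_pressure(vol[4 + i], P.s_vref[i],
                                                  P.s_p0[i], P.s_e0[i],
                                                  P.s_linear[i] != 0) + ext;
        }

        // 4. algebraic flows (resistive branches, Gorlin shunts) from the
        // elastic pressures
        for (int a = 0; a < P.nalg; ++a) {
            int f = P.a_from[a], t = P.a_to[a];
            double R = 0.0;
            if (f >= 4) R += 0.5 * seg_Rnow(f - 4, vol[f]);
            if (t >= 4) R += 0.5 * seg_Rnow(t - 4, vol[t]);
            if (R < 1e-8) R = 1e-8;
            W.q_alg[a] = (pel[f] - pel[t]) / R;
        }
        for (int s = 0; s < P.nsh; ++s) {
            if (P.sh_area[s] <= 0.0) { W.q_sh[s] = 0.0; continue; }
            double dp = pel[P.sh_c1[s]] - pel[P.sh_c2[s]];
            W.q_sh[s] = cvl::gorlin_flow(P.sh_area[s], dp, P.gorlin_c, P.grav);
        }

        // 5. net volume rates
        std::vector<double>& vd = W.vdot;
        std::fill(vd.begin(), vd.end(), 0.0);
        for (int e = 0; e < nq; ++e) {
            vd[P.e_from[e]] -= qe[e];
            vd[P.e_to[e]] += qe[e];
        }
        for (int k = 0; k < 4; ++k) {
            vd[P.v_up[k]] -= qv[k];
            vd[P.v_dn[k]] += qv[k];
        }
        for (int a = 0; a < P.nalg; ++a) {
            vd[P.a_from[a]] -= W.q_alg[a];
            vd[P.a_to[a]] += W.q_alg[a];
        }
        for (int s = 0; s < P.nsh; ++s) {
            vd[P.sh_c1[s]] -= W.q_sh[s];
            vd[P.sh_c2[s]] += W.q_sh[s];
        }

        // 6. add viscous wall terms to get luminal pressures
        for (int c = 0; c < 4; ++c) pel[c] += P.rwall[c] * vd[c];
        for (int i = 0; i < P.nseg; ++i) {
            double v = vol[4 + i];
            double inow = seg_Inow(i, v);
            double enow = seg_Enow(i, v);
            double om = cvl::wall_damping(inow, enow, P.s_lam[i]);
            pel[4 + i] += om * vd[4 + i];
        }

        // 7. state derivatives
        for (int i = 0; i < nc; ++i) dx[i] = vd[i];
        for (int e = 0; e < nq; ++e) {
            int f = P.e_from[e], t = P.e_to[e];
            double R = 0.0, I = 0.0;
            if (f >= 4) {
                R += 0.5 * seg_Rnow(f - 4, vol[f]);
                I += 0.5 * seg_Inow(f - 4, vol[f]);
            }
            if (t >= 4) {
                R += 0.5 * seg_Rnow(t - 4, vol[t]);
                I += 0.5 * seg_Inow(t - 4, vol[t]);
            }
            // keep every flow state resolvable at the 0.25 ms step
            if (I < 5e-5) I = 5e-5;
            dx[nc + e] = (pel[f] - pel[t] - R * qe[e]) / I;
        }
        for (int k = 0; k < 4; ++k) {
            double z = std::min(std::max(ze[k], 0.0), 1.0);
            double a_eff = P.v_amin[k] + (P.v_amax[k] - P.v_amin[k]) * z;
            if (a_eff < 1e-4) a_eff = 1e-4;
            double L = cvl::valve_inertance(a_eff, P.rho);
            double B = cvl::bernoulli_gradient(qv[k], a_eff, P.rho);
            double dp = pel[P.v_up[k]] - pel[P.v_dn[k]];
            dx[nc + nq + k] =
                (dp - B - P.routflow[P.v_up[k]] * qv[k]) / L;
            // the (1 - zeta) / zeta factors bound the dynamics; the
            // solved state is additionally clamped to [0, 1] after each
            // accepted step
            dx[nc + nq + 4 + k] =
                cvl::zeta_rate(ze[k], dp, P.v_ko[k], P.v_kc[k]);
        }
    }

    double wrms(const arma::vec& dy, const arma::vec& y) const {
        const int nc = P.ncomp(), nq = P.nq, nx = P.nx();
        double s = 0.0;
        for (int i = 0; i < nx; ++i) {
            double typ = (i < nc + nq + 4) ? 100.0 : 1.0;
            double sc = P.tol * (typ + std::fabs(y[i]));
            double r = dy[i] / sc;
            s += r * r;
        }
        return std::sqrt(s / nx);
    }

    void compute_jac(const arma::vec& x, double phase, double dt) {
        const int nx = P.nx();
        arma::mat J(nx, nx);
        arma::vec f0(nx), f1(nx), xp = x;
        rhs(x.memptr(), phase, f0.memptr());
        for (int j = 0; j < nx; ++j) {
            double typ = (j < P.ncomp() + P.nq + 4) ? 1.0 : 1e-2;
            double h = 1e-7 * std::max(std::fabs(x[j]), typ);
            xp[j] = x[j] + h;
            rhs(xp.memptr(), phase, f1.memptr());
            xp[j] = x[j];
            for (int i = 0; i < nx; ++i)
                J(i, j) = ((i == j) ? 1.0 : 0.0) - dt * (f1[i] - f0[i]) / h;
        }
        bool ok = arma::inv(Jinv, J);
        if (!ok) stop("solver failure: singular implicit-Euler Jacobian");
        jac_valid = true; steps_since_jac = 0; jac_dt = dt;
        ++jac_count;
    }

    // one implicit-Euler solve; returns false on Newton failure
    int fail_reason = 0;   // 1 non-finite, 2 bounds, 3 maxit
    double cur_t = 0.0;
    bool newton(const arma::vec& x, double phase_new, double dt,
                arma::vec& y) {
        const int nx = P.nx();
        arma::vec f(nx), F(nx), dy(nx);
        y = x;
        for (int it = 0; it < P.maxit; ++it) {
            rhs(y.memptr(), phase_new, f.memptr());
            F = y - x - dt * f;
            if (!F.is_finite()) { fail_reason = 1; return false; }
            dy = Jinv * F;
            y -= dy;
            ++newton_iters;
            // converged when the correction is negligible or the
            // backward-Euler residual itself is already at tolerance
            if (wrms(dy, y) < 1.0 || wrms(F, y) < 1.0) {
                // reject spurious roots: volumes positive, and no state
                // moving further in one (sub)step than physically
                // plausible rates allow
                double dvmax = 5000.0 * dt + 0.05;    // ml
                double dqmax = 1e06 * dt + 2.0;       // ml/s
                for (int i = 0; i < P.ncomp(); ++i)
                    if (!(y[i] > 1e-06 && std::fabs(y[i] - x[i]) < dvmax)) {
                        fail_reason = 200 + i;
                        return false;
                    }
                for (int i = P.ncomp(); i < P.ncomp() + P.nq + 4; ++i)
                    if (!(std::fabs(y[i] - x[i]) < dqmax)) {
                        fail_reason = 400 + i; return false;
                    }
                for (int k = 0; k < 4; ++k) {
                    int iz = P.ncomp() + P.nq + 4 + k;
                    y[iz] = std::min(std::max(y[iz], 0.0), 1.0);
                }
                return true;
            }
        }
        fail_reason = 3;
        return false;
    }

    // advance one step of size dt (recursing into halves on failure)
    void step(arma::vec& x, double& phase, double dt, int depth) {
        if (depth > 10) {
            arma::vec ftmp(P.nx());
            rhs(x.memptr(), phase, ftmp.memptr());
            int worst = arma::abs(ftmp).index_max();
            stop("solver failure: step size underflow (instability) near "
                 "state %d at t = %g s [reason %d]", worst + 1, cur_t,
                 fail_reason);
        }
        double phase_new = phase + dt / period;
        if (!jac_valid || steps_since_jac >= P.jacint ||
            std::fabs(jac_dt - dt) > 1e-15)
            compute_jac(x, phase, dt);
        arma::vec y;
        if (!newton(x, phase_new, dt, y)) {
            compute_jac(x, phase, dt);
            if (!newton(x, phase_new, dt, y)) {
                ++substeps;
                jac_valid = false;
                step(x, phase, 0.5 * dt, depth + 1);
                step(x, phase, 0.5 * dt, depth + 1);
                jac_valid = false;
                return;
            }
        }
        ++steps_since_jac;
        x = y;
        phase = phase_new;
    }

    // oxygen sub-step: upwind convection over every branch plus the
    // pulmonary source and the systemic / myocardial sinks; conservative in
    // O2 content.
    void o2_step(const arma::vec& x_old, const arma::vec& x_new,
                 std::vector<double>& sat, double dt) {
        const int nc = P.ncomp(), nq = P.nq;
        const double kHb = cvl::O2_K * P.hb;
        static thread_local std::vector<double> C, outflow;
        C.assign(nc, 0.0); outflow.assign(nc, 0.0);
        for (int i = 0; i < nc; ++i) C[i] = kHb * sat[i] * x_old[i];

        // gather every branch as (from, to, q); the donor compartment
        // loses content at its own saturation; blood entering the
        // pulmonary capillary bed arrives oxygenated to the flow-weighted
        // shunt mixture, the difference being alveolar uptake.
        auto transfer = [&](int f, int t, double q) {
            if (q == 0.0) return;
            int dn = (q > 0.0) ? f : t;
            int into = (q > 0.0) ? t : f;
            double s_out = sat[dn], s_in = s_out;
            if (into == P.o2_pulm_cap) {
                s_in = cvl::pulmonary_mix(s_out, P.shunt_frac, P.sat_cap);
                o2_pulm_in += kHb * std::fabs(q) * dt * (s_in - s_out);
            }
            double aq = kHb * std::fabs(q) * dt;
            C[dn] -= aq * s_out;
            C[into] += aq * s_in;
            if (q > 0.0) outflow[f] += q; else outflow[t] -= q;
        };
        for (int e = 0; e < nq; ++e)
            transfer(P.e_from[e], P.e_to[e], x_new[nc + e]);
        for (int k = 0; k < 4; ++k)
            transfer(P.v_up[k], P.v_dn[k], x_new[nc + nq + k]);
        for (int a = 0; a < P.nalg; ++a)
            transfer(P.a_from[a], P.a_to[a], W.q_alg[a]);
        for (int s = 0; s < P.nsh; ++s)
            transfer(P.sh_c1[s], P.sh_c2[s], W.q_sh[s]);

        // systemic consumption, distributed across the capillary sink
        // compartments in proportion to their outflow
        double need = P.vo2_sys / 60.0 * dt;
        if (need > 0.0 && !P.o2_sys_sinks.empty()) {
            double wtot = 0.0;
            for (int c : P.o2_sys_sinks) wtot += outflow[c];
            for (size_t j = 0; j < P.o2_sys_sinks.size(); ++j) {
                int c = P.o2_sys_sinks[j];
                double w = (wtot > 0.0) ? outflow[c] / wtot
                                        : 1.0 / P.o2_sys_sinks.size();
                double rm = std::min(need * w, std::max(C[c], 0.0));
                if (rm < need * w) ++sat_clamps;
                C[c] -= rm;
                o2_sys_out += rm;
            }
        }
        // myocardial consumption from the coronary microvascular blood
        for (int s = 0; s < 2; ++s) {
            int c = P.o2_myo_sink[s];
            if (c < 0) continue;
            double needm = vo2_myo[s] / 60.0 * dt;
            double rm = std::min(needm, std::max(C[c], 0.0));
            if (rm < needm) ++sat_clamps;
            C[c] -= rm;
            o2_myo_out += rm;
        }
        for (int i = 0; i < nc; ++i) {
            double s = C[i] / (kHb * x_new[i]);
            if (s < 0.0) { s = 0.0; ++sat_clamps; }
            if (s > 100.0) { s = 100.0; ++sat_clamps; }
            sat[i] = s;
        }
    }

    void finalize_beat(const arma::vec& x, double t) {
        // pressure-volume area -> myocardial oxygen rate, per ventricle
        for (int s = 0; s < 2; ++s) {
            double pe = std::max(0.5 * pes[s] * (ves[s] - P.v0[s]), 0.0);
            double pva = std::max(sw_acc[s], 0.0) + pe;
            double vo2_beat =
                (P.pva_a * pva + P.pva_b * ees[s] + P.pva_c) * P.mass[s] /
                100.0;
            vo2_myo[s] = vo2_beat * 60.0 / period;
        }
        beat_rows.insert(beat_rows.end(),
                         {beat_t0, t, period, sw_acc[0], sw_acc[1], pes[0],
                          ves[0], pes[1], ves[1], ees[0], ees[1], vo2_myo[0],
                          vo2_myo[1], (double)osc_count});
        ++n_beat_rows;
        if (osc_count > osc_max) osc_max = osc_count;
        osc_count = 0;
        for (int s = 0; s < 2; ++s) {
            sw_acc[s] = 0.0; es_done[s] = false;
        }
        beat_t0 = t;
        // next period: baroreflex heart-rate multiplier and AF jitter
        double jf = 1.0;
        if (P.af_on && P.af_jitter > 0.0) {
            rng = rng * 1664525u + 1013904223u;
            double u = rng / 4294967296.0;
            jf = 1.0 + P.af_jitter * (2.0 * u - 1.0);
        }
        double hr_eff = P.hr * m_hr;
        set_beat_params(60.0 / hr_eff * jf);
    }

    void beat_accumulate(const arma::vec& x, double phase_prev,
                         double phase) {
        // stroke work, end-systolic capture, oscillation counting
        for (int s = 0; s < 2; ++s) {
            double p = W.p_lum[s] - (P.p_thorax + W.p_peri);
            double v = x[s];
            sw_acc[s] += 0.5 * (p + prev_plv[s]) * (prev_v[s] - v);
            prev_plv[s] = p; prev_v[s] = v;
            if (!es_done[s]) {
                double target = espf[s];
                if (phase >= target && phase_prev < target) {
                    pes[s] = p; ves[s] = v;
                    ees[s] = emax_eff(s, v);
                    es_done[s] = true;
                }
            }
        }
        // turning-point counter with 0.25 mmHg deadband on the monitored
        // pressure (ringing detector; see vignette)
        double p = W.p_lum[P.osc_comp];
        if (osc_dir == 0) {
            osc_extreme = p; osc_dir = 1;
        } else if (osc_dir > 0) {
            if (p > osc_extreme) osc_extreme = p;
            else if (p < osc_extreme - 0.25) { osc_dir = -1; osc_extreme = p; ++osc_count; }
        } else {
            if (p < osc_extreme) osc_extreme = p;
            else if (p > osc_extreme + 0.25) { osc_dir = 1; osc_extreme = p; ++osc_count; }
        }
    }
};

} // namespace

// [[Rcpp::export(name = "cpp_rhs")]]
NumericVector cpp_rhs(List pack, NumericVector x, double phase) {
    Pack P = parse_pack(pack);
    Engine E(P);
    NumericVector dx(P.nx());
    if ((int)x.size() != P.nx()) stop("state length mismatch");
    E.rhs(REAL(x), phase, REAL(dx));
    return dx;
}

// [[Rcpp::export(name = "cpp_advance")]]
List cpp_advance(List pack, List state, double t_end, double record_dt) {
    Pack P = parse_pack(pack);
    Engine E(P);

    arma::vec x = as<arma::vec>(state["x"]);
    if ((int)x.n_elem != P.nx()) stop("state length mismatch");
    std::vector<double> sat = as<std::vector<double>>(state["sat"]);
    double t = getd(state, "t");
    double phase = getd(state, "phase");
    int beat = geti(state, "beat");
    NumericVector vm = state["vo2_myo"];
    E.vo2_myo[0] = vm[0]; E.vo2_myo[1] = vm[1];
    E.baro_f = getd(state, "baro_f");
    E.m_hr = getd(state, "m_hr"); E.m_em = getd(state, "m_em");
    E.m_res = getd(state, "m_res");
    E.rng = (uint32_t)getd(state, "rng");
    double per = getd(state, "period");
    E.set_beat_params(per);
    E.beat_t0 = t;

    const int nc = P.ncomp(), nq = P.nq;
    // trace allocation
    int ncol = 10 + 3 * nc + nq + 4 + 4 + P.nalg + P.nsh;
    int max_rows = (record_dt > 0.0)
        ? (int)std::floor((t_end - t) / record_dt + 1e-9) + 2 : 0;
    NumericMatrix trace(std::max(max_rows, 0), ncol);
    int nrow = 0;
    double next_rec = (record_dt > 0.0)
        ? std::ceil((t - 1e-12) / record_dt) * record_dt : 2.0 * t_end + 1.0;
    if (next_rec < t) next_rec = t;

    // initialise previous-step beat accumulator values
    {
        arma::vec f(P.nx());
        E.rhs(x.memptr(), phase, f.memptr());
        for (int s = 0; s < 2; ++s) {
            E.prev_plv[s] = E.W.p_lum[s] - (P.p_thorax + E.W.p_peri);
            E.prev_v[s] = x[s];
        }
    }

    auto record = [&](double tt, double ph) {
        if (nrow >= trace.nrow()) return;
        int j = 0;
        trace(nrow, j++) = tt;
        trace(nrow, j++) = beat;
        trace(nrow, j++) = ph;
        trace(nrow, j++) = E.ecg(ph);
        trace(nrow, j++) = P.p_thorax;
        trace(nrow, j++) = E.W.p_peri;
        trace(nrow, j++) = 60.0 / E.period;
        trace(nrow, j++) = E.m_hr;
        trace(nrow, j++) = E.m_em;
        trace(nrow, j++) = E.m_res;
        for (int i = 0; i < nc; ++i) trace(nrow, j++) = E.W.p_lum[i];
        for (int i = 0; i < nc; ++i) trace(nrow, j++) = x[i];
        for (int i = 0; i < nc; ++i) trace(nrow, j++) = sat[i];
        for (int e = 0; e < nq; ++e) trace(nrow, j++) = x[nc + e];
        for (int k = 0; k < 4; ++k) trace(nrow, j++) = x[nc + nq + k];
        for (int k = 0; k < 4; ++k) trace(nrow, j++) = x[nc + nq + 4 + k];
        for (int a = 0; a < P.nalg; ++a) trace(nrow, j++) = E.W.q_alg[a];
        for (int s = 0; s < P.nsh; ++s) trace(nrow, j++) = E.W.q_sh[s];
        ++nrow;
    };

    // W is valid from the initialisation rhs call
    if (t >= next_rec - 1e-12) { record(t, phase); next_rec += record_dt; }

    arma::vec x_old = x;
    long total_steps = 0;
    while (t < t_end - 1e-12) {
        double dt = std::min(P.dt, t_end - t);
        double phase_prev = phase;
        x_old = x;
        E.cur_t = t;
        bool roll = (phase + dt / E.period >= 1.0);
        E.step(x, phase, dt, 0);
        t += dt;
        ++total_steps;
        if (total_steps % 4000 == 0) Rcpp::checkUserInterrupt();
        // refresh work buffers at the accepted state
        {
            static thread_local std::vector<double> fbuf;
            fbuf.assign(P.nx(), 0.0);
            E.rhs(x.memptr(), phase, fbuf.data());
        }
        if (!x.is_finite())
            stop("solver instability: non-finite state at t = %f", t);
        for (int i = 0; i < nc; ++i)
            if (x[i] <= 0.0)
                stop("solver failure: non-positive volume in compartment %d "
                     "at t = %f (collapse is not modelled)", i + 1, t);
        E.o2_step(x_old, x, sat, dt);
        // baroreflex sensing (first-order filter on the sensed pressure)
        if (P.baro_on) {
            E.baro_f += dt * (E.W.p_lum[P.baro_sense] - E.baro_f) /
                P.baro_tau;
            double ef = (P.baro_setp - E.baro_f) / P.baro_setp;
            auto clampm = [&](double m) {
                return std::min(std::max(m, P.baro_mmin), P.baro_mmax);
            };
            E.m_em = clampm(1.0 + P.baro_gem * ef);
            E.m_res = clampm(1.0 + P.baro_gres * ef);
            E.m_hr = clampm(1.0 + P.baro_ghr * ef);
        }
        E.beat_accumulate(x, phase_prev, phase);
        if (roll) {
            E.finalize_beat(x, t);
            phase -= 1.0;
            ++beat;
        }
        if (t >= next_rec - 1e-12) {
            record(t, phase);
            next_rec += record_dt;
        }
    }

    NumericMatrix tr(nrow, ncol);
    for (int i = 0; i < nrow; ++i)
        for (int j = 0; j < ncol; ++j) tr(i, j) = trace(i, j);

    NumericMatrix beats(E.n_beat_rows, 14);
    for (int i = 0; i < E.n_beat_rows; ++i)
        for (int j = 0; j < 14; ++j) beats(i, j) = E.beat_rows[i * 14 + j];

    List out_state = List::create(
        _["x"] = NumericVector(x.begin(), x.end()),
        _["sat"] = NumericVector(sat.begin(), sat.end()),
        _["t"] = t, _["phase"] = phase, _["period"] = E.period,
        _["beat"] = beat,
        _["vo2_myo"] = NumericVector::create(E.vo2_myo[0], E.vo2_myo[1]),
        _["baro_f"] = E.baro_f, _["m_hr"] = E.m_hr, _["m_em"] = E.m_em,
        _["m_res"] = E.m_res, _["rng"] = (double)E.rng);

    List diag = List::create(
        _["o2_pulm_in"] = E.o2_pulm_in, _["o2_sys_out"] = E.o2_sys_out,
        _["o2_myo_out"] = E.o2_myo_out,
        _["newton_iters"] = (double)E.newton_iters,
        _["jac_count"] = (double)E.jac_count,
        _["substeps"] = (double)E.substeps,
        _["sat_clamps"] = (double)E.sat_clamps,
        _["osc_max"] = E.osc_max,
        _["steps"] = (double)total_steps);

    return List::create(_["state"] = out_state, _["trace"] = tr,
                        _["beats"] = beats, _["diag"] = diag);
}

// Standalone oxygen advection stepper over a fixed flow field: used to
// check the transport scheme against closed-form two-compartment solutions
// and for conservation property tests.
// [[Rcpp::export(name = "cpp_o2_advect")]]
NumericVector cpp_o2_advect(NumericVector volume, NumericVector sat0,
                            IntegerVector from, IntegerVector to,
                            NumericVector q, double hb, double dt,
                            int n_steps) {
    int nc = volume.size(), ne = from.size();
    std::vector<double> sat(sat0.begin(), sat0.end());
    std::vector<double> C(nc);
    const double kHb = cvl::O2_K * hb;
    for (int s = 0; s < n_steps; ++s) {
        for (int i = 0; i < nc; ++i) C[i] = kHb * sat[i] * volume[i];
        for (int e = 0; e < ne; ++e) {
            double qq = q[e];
            if (qq == 0.0) continue;
            int dn = (qq > 0.0) ? from[e] : to[e];
            double m = kHb * std::fabs(qq) * dt * sat[dn];
            double sgn = (qq > 0.0) ? 1.0 : -1.0;
            C[from[e]] -= sgn * m;
            C[to[e]] += sgn * m;
        }
        for (int i = 0; i < nc; ++i) sat[i] = C[i] / (kHb * volume[i]);
    }
    return NumericVector(sat.begin(), sat.end());
}
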