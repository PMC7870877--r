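#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Double-Hill activation drive, un-normalized. tn is the fraction of the
// beat elapsed, in [0, 1); tau1/tau2 are in the same normalized units.
static inline double hill_raw(double tn, double tau1, double tau2,
                              double m1, double m2) {
  if (tn <= 0.0) return 0.0;
  double g1 = std::pow(tn / tau1, m1);
  double g2 = std::pow(tn / tau2, m2);
  return (g1 / (1.0 + g1)) * (1.0 / (1.0 + g2));
}

struct SimPar {
  double Ees, V0_base, sda_a, sda_b;
  bool sda_on;
  double edA, edB, edV0d;
  double Rc, Rp, Ca, Cv, Cvc, Rm, Rv;
  double tau1, tau2, m1, m2, act_norm;
  double fs;
};

// Activation at absolute time t given the beat table (onsets contiguous).
// *hint is an advance-only cursor: stage times are non-decreasing.
static inline double activation_at(double t, const NumericVector& onset,
                                   const NumericVector& period,
                                   const NumericVector& amp,
                                   int* hint, const SimPar& P) {
  int j = *hint;
  int nb = onset.size();
  while (j + 1 < nb && t >= onset[j + 1]) j++;
  *hint = j;
  double tn = (t - onset[j]) / period[j];
  if (tn < 0.0) tn = 0.0;
  if (tn >= 1.0) tn = 1.0 - 1e-12;
  return amp[j] * hill_raw(tn, P.tau1, P.tau2, P.m1, P.m2) / P.act_norm;
}

static inline double plv_of(double Vlv, double e, double v0eff,
                            const SimPar& P) {
  double pa = P.Ees * (Vlv - v0eff);
  double pd = P.edA * std::expm1(P.edB * (Vlv - P.edV0d));
  return e * pa + (1.0 - e) * pd;
}

// Linear interpolation of a per-sample factor vector at time t (seconds).
static inline double factor_at(const NumericVector& f, double t, double fs) {
  double x = t * fs;
  int i = (int)std::floor(x);
  int n = f.size();
  if (i < 0) return f[0];
  if (i >= n - 1) return f[n - 1];
  double w = x - i;
  return f[i] * (1.0 - w) + f[i + 1] * w;
}

// Four compartments: LV -> aortic valve/Rc -> arterial Ca -> Rp ->
// peripheral venous Cv -> venous-return Rv (occlusion site) -> central
// venous Cvc -> mitral Rm -> LV.
struct Deriv { double dVlv, dVa, dVv, dVvc, plv, qao; };

static inline Deriv rhs(double t, double Vlv, double Va, double Vv,
                        double Vvc, double e, double v0eff,
                        const SimPar& P,
                        const NumericVector& rpF, const NumericVector& rvF,
                        const NumericVector& rcF) {
  double Plv = plv_of(Vlv, e, v0eff, P);
  double Pa = Va / P.Ca;
  double Pv = Vv / P.Cv;
  double Pvc = Vvc / P.Cvc;
  double rc = P.Rc * factor_at(rcF, t, P.fs);
  double rp = P.Rp * factor_at(rpF, t, P.fs);
  double rv = P.Rv * factor_at(rvF, t, P.fs);
  double qao = Plv > Pa ? (Plv - Pa) / rc : 0.0;
  double qin = Pvc > Plv ? (Pvc - Plv) / P.Rm : 0.0;
  double qr = (Pv - Pvc) / rv;
  double qp = (Pa - Pv) / rp;
  Deriv d;
  d.dVlv = qin - qao;
  d.dVa = qao - qp;
  d.dVv = qp - qr;
  d.dVvc = qr - qin;
  d.plv = Plv;
  d.qao = qao;
  return d;
}

// [[Rcpp::export]]
List simulate_core(int n, double fs,
                   NumericVector beat_onset, NumericVector beat_period,
                   NumericVector beat_amp, IntegerVector beat_start,
                   IntegerVector es_sample, IntegerVector sda_active,
                   double Ees, double V0_base, double sda_a, double sda_b,
                   bool sda_on, double sda_gain,
                   double edA, double edB, double edV0d,
                   double Rc, double Rp, double Ca, double Cv, double Cvc,
                   double Rm, double Rv,
                   double tau1, double tau2, double m1, double m2,
                   double act_norm,
                   double Vlv0, double Pa0, double total_volume,
                   NumericVector rpF, NumericVector rvF, NumericVector rcF) {
  SimPar P;
  P.Ees = Ees; P.V0_base = V0_base; P.sda_a = sda_a; P.sda_b = sda_b;
  P.sda_on = sda_on;
  P.edA = edA; P.edB = edB; P.edV0d = edV0d;
  P.Rc = Rc; P.Rp = Rp; P.Ca = Ca; P.Cv = Cv; P.Cvc = Cvc;
  P.Rm = Rm; P.Rv = Rv;
  P.tau1 = tau1; P.tau2 = tau2; P.m1 = m1; P.m2 = m2; P.act_norm = act_norm;
  P.fs = fs;

  int nb = beat_onset.size();
  double h = 1.0 / fs;

  NumericVector lvp(n), lvv(n), aop(n), aoflow(n), total(n);
  NumericVector tr_v0(nb, NA_REAL), tr_ved(nb, NA_REAL), tr_ves(nb, NA_REAL),
      tr_pes(nb, NA_REAL), tr_ea(nb, NA_REAL), tr_tes(nb, NA_REAL),
      tr_pv(nb, NA_REAL), tr_pvc(nb, NA_REAL);

  double Vlv = Vlv0;
  double Va = Ca * Pa0;
  double rest = total_volume - Vlv - Va;
  if (rest <= 0) stop("total_volume too small for the requested initial state");
  // split the venous volume so both venous compartments start at the
  // same pressure
  double Vv = rest * Cv / (Cv + Cvc);
  double Vvc = rest * Cvc / (Cv + Cvc);

  double v0eff = V0_base;  // first beat: no previous-beat Ea available
  int cur = 0, hint = 0;

  for (int i = 0; i < n; i++) {
    double t = i * h;

    // beat bookkeeping: entering beat j at its start sample
    if (cur + 1 < nb && i == beat_start[cur + 1]) {
      // finalize beat `cur`: Ea from its recorded end-systolic point
      double sv = tr_ved[cur] - tr_ves[cur];
      if (R_finite(sv) && sv > 0.1 && R_finite(tr_pes[cur]))
        tr_ea[cur] = tr_pes[cur] / sv;
      cur++;
      if (P.sda_on) {
        // V0 adapts to the afterload level: the per-beat update runs
        // only while the arterial load is (re)settling; V0_eff holds
        // otherwise, so a held afterload means a fixed ESPVR line.
        double ea_prev = tr_ea[cur - 1];
        if (sda_active[cur] && R_finite(ea_prev))
          v0eff += sda_gain * (sda_a * ea_prev + sda_b - v0eff);
      } else {
        v0eff = V0_base;
      }
    }
    tr_v0[cur] = v0eff;

    int h2 = hint;
    double e = activation_at(t, beat_onset, beat_period, beat_amp, &h2, P);
    Deriv d0 = rhs(t, Vlv, Va, Vv, Vvc, e, v0eff, P, rpF, rvF, rcF);
    lvp[i] = d0.plv;
    lvv[i] = Vlv;
    aop[i] = Va / Ca + d0.qao * (P.Rc * factor_at(rcF, t, fs));
    aoflow[i] = d0.qao;
    total[i] = Vlv + Va + Vv + Vvc;

    if (i == beat_start[cur]) {
      tr_ved[cur] = Vlv;
      tr_pv[cur] = Vv / P.Cv;
      tr_pvc[cur] = Vvc / P.Cvc;
    }
    if (es_sample[cur] == i) {
      tr_ves[cur] = Vlv;
      tr_pes[cur] = d0.plv;
      tr_tes[cur] = t;
    }

    if (i == n - 1) break;

    // classical RK4 step
    double e1 = activation_at(t, beat_onset, beat_period, beat_amp, &hint, P);
    Deriv k1 = rhs(t, Vlv, Va, Vv, Vvc, e1, v0eff, P, rpF, rvF, rcF);
    int hm = hint;
    double em = activation_at(t + 0.5 * h, beat_onset, beat_period, beat_amp,
                              &hm, P);
    Deriv k2 = rhs(t + 0.5 * h, Vlv + 0.5 * h * k1.dVlv,
                   Va + 0.5 * h * k1.dVa, Vv + 0.5 * h * k1.dVv,
                   Vvc + 0.5 * h * k1.dVvc, em, v0eff, P, rpF, rvF, rcF);
    Deriv k3 = rhs(t + 0.5 * h, Vlv + 0.5 * h * k2.dVlv,
                   Va + 0.5 * h * k2.dVa, Vv + 0.5 * h * k2.dVv,
                   Vvc + 0.5 * h * k2.dVvc, em, v0eff, P, rpF, rvF, rcF);
    int he = hm;
    double ee = activation_at(t + h, beat_onset, beat_period, beat_amp,
                              &he, P);
    Deriv k4 = rhs(t + h, Vlv + h * k3.dVlv, Va + h * k3.dVa,
                   Vv + h * k3.dVv, Vvc + h * k3.dVvc, ee, v0eff, P,
                   rpF, rvF, rcF);

    Vlv += h / 6.0 * (k1.dVlv + 2 * k2.dVlv + 2 * k3.dVlv + k4.dVlv);
    Va += h / 6.0 * (k1.dVa + 2 * k2.dVa + 2 * k3.dVa + k4.dVa);
    Vv += h / 6.0 * (k1.dVv + 2 * k2.dVv + 2 * k3.dVv + k4.dVv);
    Vvc += h / 6.0 * (k1.dVvc + 2 * k2.dVvc + 2 * k3.dVvc + k4.dVvc);

    if (!R_finite(Vlv) || !R_finite(Va) || !R_finite(Vv) ||
        !R_finite(Vvc) || Vlv < 1.0)
      stop("simulation unstable at step %d (t = %.3f s): Vlv = %.3f mL",
           i + 1, t + h, Vlv);
  }

  // finalize the last beat if its end-systolic sample was reached
  if (R_finite(tr_pes[cur]) && R_finite(tr_ved[cur])) {
    double sv = tr_ved[cur] - tr_ves[cur];
    if (sv > 0.1) tr_ea[cur] = tr_pes[cur] / sv;
  }

  return List::create(
      _["lvp"] = lvp, _["lvv"] = lvv, _["aop"] = aop, _["aoflow"] = aoflow,
      _["total"] = total,
      _["truth"] = DataFrame::create(
          _["beat"] = seq_len(nb), _["t_start_s"] = beat_onset,
          _["rr_s"] = beat_period, _["v0_eff_ml"] = tr_v0,
          _["t_es_s"] = tr_tes, _["ved_ml"] = tr_ved, _["ves_ml"] = tr_ves,
          _["pes_mmhg"] = tr_pes, _["ea_mmhg_ml"] = tr_ea,
          _["pv_mmhg"] = tr_pv, _["pvc_mmhg"] = tr_pvc));
}
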