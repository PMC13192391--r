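#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step operator-split integrator for the single-compartment plateau
// model. Per step: synaptic conductance evaluated in closed form (exact
// exponential decay, superposition over events), gates advanced by exact
// exponential relaxation toward their steady states with rates frozen at the
// step start, then (V, cai) advanced by an explicit midpoint update with the
// gates and stimulus held at their new/mid-step values. Formulas mirror the
// R reference functions in model-core.R one-to-one.

struct Params {
  double area, Cm, g_pas, E_pas, gbar_cal, tfa, ki, cao,
    gbar_kca, E_K, cac, beta_kca, tadj, depth, tau_r, ca_inf,
    E_GABA, TK, F, R_gas;
  bool clamp;
};

static inline double efun(double z) {
  if (std::fabs(z) < 1e-4) return 1.0 - z / 2.0;
  return z / (std::exp(z) - 1.0);
}

static inline void cal_rates(double V, const Params &p,
                             double &minf, double &tau) {
  double u = -27.01 - V;
  double a = 0.055 * 3.8 * efun(u / 3.8);
  double b = 0.94 * std::exp((-63.01 - V) / 17.0);
  minf = a / (a + b);
  tau = 1.0 / (p.tfa * (a + b));
}

static inline void kca_gate(double cai, const Params &p,
                            double &minf, double &tau) {
  double r2 = (cai / p.cac) * (cai / p.cac);
  minf = r2 / (1.0 + r2);
  tau = 1.0 / (p.beta_kca * (1.0 + r2)) / p.tadj;
}

static inline double ghk(double V, double cai, const Params &p) {
  double z = 2.0 * p.F * V * 1e-3 / (p.R_gas * p.TK);
  return 1e-3 * 2.0 * p.F * (cai * efun(-z) - p.cao * efun(z));
}

static inline double i_vgcc(double V, double m, double cai, const Params &p) {
  double h = p.ki / (p.ki + cai);
  return p.gbar_cal * m * h * h * ghk(V, cai, p);
}

// Exponential update of (V, cai) over step h: the ohmic currents (leak, SK,
// synapse) define a linear relaxation integrated exactly; the GHK current is
// frozen at (Vf, caf). Writes the relaxed values into V and cai.
static inline void vc_exp_step(double &V, double &cai, double m_cal,
                               double m_kca, double g_syn_uS, double I_inj,
                               double Vf, double caf, double h,
                               const Params &p) {
  double gk = p.gbar_kca * m_kca * m_kca * m_kca;
  double gs = g_syn_uS * 1e-6 / p.area;
  double Ica = i_vgcc(Vf, m_cal, caf, p);
  double a = 1000.0 / p.Cm * (p.g_pas + gk + gs);          // 1/ms
  double b = 1000.0 / p.Cm * (p.g_pas * p.E_pas + gk * p.E_K +
                              gs * p.E_GABA + I_inj - Ica); // mV/ms
  double Vinf = b / a;
  V = Vinf + (V - Vinf) * std::exp(-a * h);
  double drive = -1e4 * Ica / (2.0 * p.F * p.depth);
  if (p.clamp && drive < 0.0) drive = 0.0;
  double cinf = p.ca_inf + p.tau_r * drive;
  cai = cinf + (cai - cinf) * std::exp(-h / p.tau_r);
  if (cai < 0.0) cai = 0.0;
}

// stimulus at absolute time t
static inline double stim_current(double t, const NumericMatrix &steps,
                                  const NumericMatrix &ipsps) {
  double I = 0.0;
  for (int i = 0; i < steps.nrow(); ++i) {
    if (t >= steps(i, 0) && t < steps(i, 0) + steps(i, 1)) I += steps(i, 2);
  }
  for (int i = 0; i < ipsps.nrow(); ++i) {
    if (t >= ipsps(i, 0)) I -= ipsps(i, 1) * std::exp(-(t - ipsps(i, 0)) / ipsps(i, 2));
  }
  return I;
}

static inline double syn_conductance(double t, const NumericMatrix &ipsgs) {
  double g = 0.0;
  for (int i = 0; i < ipsgs.nrow(); ++i) {
    if (t >= ipsgs(i, 0)) g += ipsgs(i, 1) * std::exp(-(t - ipsgs(i, 0)) / ipsgs(i, 2));
  }
  return g;
}

// [[Rcpp::export(name = ".integrate_model")]]
List integrate_model(List params, NumericVector init, double t0,
                     double duration, double dt,
                     NumericMatrix steps, NumericMatrix ipsps,
                     NumericMatrix ipsgs, int record_every) {
  Params p;
  p.area = params["area"]; p.Cm = params["Cm"];
  p.g_pas = params["g_pas"]; p.E_pas = params["E_pas"];
  p.gbar_cal = params["gbar_cal"]; p.tfa = params["tfa"];
  p.ki = params["ki"]; p.cao = params["cao"];
  p.gbar_kca = params["gbar_kca"]; p.E_K = params["E_K"];
  p.cac = params["cac"]; p.beta_kca = params["beta_kca"];
  p.depth = params["depth"]; p.tau_r = params["tau_r"];
  p.ca_inf = params["ca_inf"]; p.E_GABA = params["E_GABA"];
  p.F = params["F"]; p.R_gas = params["R_gas"];
  double temperature = params["temperature"];
  double q10 = params["q10_kca"], tref = params["temp_ref_kca"];
  p.TK = temperature + 273.15;
  p.tadj = std::pow(q10, (temperature - tref) / 10.0);
  p.clamp = as<bool>(params["ca_drive_clamp"]);

  long nstep = (long)std::llround(duration / dt);
  double V = init[0], m_cal = init[1], m_kca = init[2], cai = init[3];

  long nrec = (record_every > 0) ? (nstep / record_every + 1) : 0;
  NumericMatrix rec(nrec, 7);

  long ri = 0;
  for (long i = 0; i <= nstep; ++i) {
    double t = t0 + i * dt;
    if (record_every > 0 && (i % record_every == 0) && ri < nrec) {
      rec(ri, 0) = t; rec(ri, 1) = V; rec(ri, 2) = m_cal; rec(ri, 3) = m_kca;
      rec(ri, 4) = cai; rec(ri, 5) = syn_conductance(t, ipsgs);
      rec(ri, 6) = stim_current(t, steps, ipsps);
      ++ri;
    }
    if (i == nstep) break;

    // gates: exact exponential relaxation, rates frozen at step start
    double minf, tau;
    cal_rates(V, p, minf, tau);
    m_cal += (minf - m_cal) * (1.0 - std::exp(-dt / tau));
    kca_gate(cai, p, minf, tau);
    m_kca += (minf - m_kca) * (1.0 - std::exp(-dt / tau));

    // midpoint-style exponential update of V, cai with the new gates and
    // the stimulus evaluated at mid-step: predictor relaxes a half step
    // with GHK frozen at the step start, corrector does the full step with
    // GHK frozen at the predicted midpoint
    double tm = t + dt / 2.0;
    double g_mid = syn_conductance(tm, ipsgs);
    double I_mid = stim_current(tm, steps, ipsps);
    double Vm = V, cm = cai;
    vc_exp_step(Vm, cm, m_cal, m_kca, g_mid, I_mid, V, cai, dt / 2.0, p);
    vc_exp_step(V, cai, m_cal, m_kca, g_mid, I_mid, Vm, cm, dt, p);

    if (!std::isfinite(V) || !std::isfinite(cai)) {
      stop("numerical failure: non-finite state at t = %f ms", t);
    }
    if (std::fabs(V) > 200.0) {
      stop("numerical blow-up: |V| > 200 mV at t = %f ms", t);
    }
  }

  NumericVector fin = NumericVector::create(V, m_cal, m_kca, cai);
  return List::create(_["record"] = rec, _["final"] = fin);
}
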