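#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Connor-Stevens kinetics (Dayan & Abbott parameterization; V in mV, t in ms).
// The linear-over-expm1 terms are evaluated with a series guard at the
// removable singularity.

static inline double vtrap(double x, double scale) {
  // x / (1 - exp(-x/scale)), safe near x = 0
  double y = x / scale;
  if (std::fabs(y) < 1e-7) return scale * (1.0 + y / 2.0);
  return x / (1.0 - std::exp(-y));
}

struct CSParams {
  double C;
  double gNa, gK, gA, gL;
  double ENa, EK, EA, EL;
};

struct CSState {
  double V, m, h, n, a, b;
};

static inline double alpha_m(double V) { return 0.38 * vtrap(V + 29.7, 10.0); }
static inline double beta_m(double V)  { return 15.2 * std::exp(-0.0556 * (V + 54.7)); }
static inline double alpha_h(double V) { return 0.266 * std::exp(-0.05 * (V + 48.0)); }
static inline double beta_h(double V)  { return 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0))); }
static inline double alpha_n(double V) { return 0.02 * vtrap(V + 45.7, 10.0); }
static inline double beta_n(double V)  { return 0.25 * std::exp(-0.0125 * (V + 55.7)); }

static inline double a_inf(double V) {
  double num = 0.0761 * std::exp(0.0314 * (V + 94.22));
  double den = 1.0 + std::exp(0.0346 * (V + 1.17));
  return std::cbrt(num / den);
}
static inline double tau_a(double V) {
  return 0.3632 + 1.158 / (1.0 + std::exp(0.0497 * (V + 55.96)));
}
static inline double b_inf(double V) {
  double y = 1.0 / (1.0 + std::exp(0.0688 * (V + 53.3)));
  return y * y * y * y;
}
static inline double tau_b(double V) {
  return 1.24 + 2.678 / (1.0 + std::exp(0.0624 * (V + 50.0)));
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Exponential (Rush-Larsen) gate update over dt at frozen voltage V.
// Each gate relaxes exactly toward its steady state: unconditionally stable,
// which matters because 1/(alpha_m + beta_m) drops below the step size when
// the cell is strongly hyperpolarized.
static inline void gates_rl(CSState& s, double V, double dt) {
  double am = alpha_m(V), bm = beta_m(V);
  double ah = alpha_h(V), bh = beta_h(V);
  double an = alpha_n(V), bn = beta_n(V);
  double minf = am / (am + bm), hinf = ah / (ah + bh), ninf = an / (an + bn);
  s.m = clamp01(minf + (s.m - minf) * std::exp(-dt * (am + bm)));
  s.h = clamp01(hinf + (s.h - hinf) * std::exp(-dt * (ah + bh)));
  s.n = clamp01(ninf + (s.n - ninf) * std::exp(-dt * (an + bn)));
  double ai = a_inf(V), bi = b_inf(V);
  s.a = clamp01(ai + (s.a - ai) * std::exp(-dt / tau_a(V)));
  s.b = clamp01(bi + (s.b - bi) * std::exp(-dt / tau_b(V)));
}

static inline double v_deriv(double V, const CSState& g, double Iext,
                             const CSParams& p) {
  double INa = p.gNa * g.m * g.m * g.m * g.h * (p.ENa - V);
  double IK  = p.gK  * g.n * g.n * g.n * g.n * (p.EK - V);
  double IA  = p.gA  * g.a * g.a * g.a * g.b * (p.EA - V);
  double IL  = p.gL  * (p.EL - V);
  return (INa + IK + IA + IL + Iext) / p.C;
}

// One fixed step with zero-order-held external current: Strang split of a
// Rush-Larsen gate update around a classical RK4 step of the (non-stiff)
// voltage equation with frozen gates.
static inline CSState rk4_step(const CSState& s, double Iext, double h, const CSParams& p) {
  CSState r = s;
  gates_rl(r, s.V, h / 2.0);
  double k1 = v_deriv(r.V, r, Iext, p);
  double k2 = v_deriv(r.V + h / 2.0 * k1, r, Iext, p);
  double k3 = v_deriv(r.V + h / 2.0 * k2, r, Iext, p);
  double k4 = v_deriv(r.V + h * k3, r, Iext, p);
  r.V = r.V + h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  gates_rl(r, r.V, h / 2.0);
  return r;
}

static CSParams as_cs_params(const List& params) {
  CSParams p;
  p.C   = as<double>(params["C"]);
  p.gNa = as<double>(params["g_na"]);
  p.gK  = as<double>(params["g_k"]);
  p.gA  = as<double>(params["g_a"]);
  p.gL  = as<double>(params["g_l"]);
  p.ENa = as<double>(params["e_na"]);
  p.EK  = as<double>(params["e_k"]);
  p.EA  = as<double>(params["e_a"]);
  p.EL  = as<double>(params["e_l"]);
  return p;
}

// [[Rcpp::export(name = ".cs_integrate_cpp")]]
List cs_integrate_cpp(List params, NumericVector state0, double h,
                      NumericVector i_inj, NumericVector i_noise) {
  CSParams p = as_cs_params(params);
  int n_steps = i_inj.size();
  if (i_noise.size() != n_steps) stop("i_inj and i_noise must have the same length");
  CSState s;
  s.V = state0[0]; s.m = state0[1]; s.h = state0[2];
  s.n = state0[3]; s.a = state0[4]; s.b = state0[5];

  NumericVector V(n_steps + 1);
  NumericMatrix gating(n_steps + 1, 5);
  V[0] = s.V;
  gating(0, 0) = s.m; gating(0, 1) = s.h; gating(0, 2) = s.n;
  gating(0, 3) = s.a; gating(0, 4) = s.b;

  for (int k = 0; k < n_steps; ++k) {
    double Iext = i_inj[k] + i_noise[k];
    s = rk4_step(s, Iext, h, p);
    if (!std::isfinite(s.V)) {
      stop("integration failure: non-finite membrane voltage at t = %f ms",
           (k + 1) * h);
    }
    V[k + 1] = s.V;
    gating(k + 1, 0) = s.m; gating(k + 1, 1) = s.h; gating(k + 1, 2) = s.n;
    gating(k + 1, 3) = s.a; gating(k + 1, 4) = s.b;
  }
  return List::create(_["v"] = V, _["gating"] = gating);
}

// Steady-state gating at a given voltage (used for initial conditions).
// [[Rcpp::export(name = ".cs_gating_inf_cpp")]]
NumericVector cs_gating_inf_cpp(double V) {
  NumericVector g(5);
  g[0] = alpha_m(V) / (alpha_m(V) + beta_m(V));
  g[1] = alpha_h(V) / (alpha_h(V) + beta_h(V));
  g[2] = alpha_n(V) / (alpha_n(V) + beta_n(V));
  g[3] = a_inf(V);
  g[4] = b_inf(V);
  return g;
}

// ---- stateful plant for closed-loop control ----------------------------

class CSPlant {
public:
  CSPlant(const CSParams& p, const CSState& s, double h) : p_(p), s_(s), h_(h) {}
  double step(double i_inj, const NumericVector& i_noise) {
    for (int k = 0; k < i_noise.size(); ++k) {
      s_ = rk4_step(s_, i_inj + i_noise[k], h_, p_);
      if (!std::isfinite(s_.V))
        stop("integration failure: non-finite membrane voltage in plant step");
    }
    return s_.V;
  }
  double voltage() const { return s_.V; }
  NumericVector state() const {
    return NumericVector::create(s_.V, s_.m, s_.h, s_.n, s_.a, s_.b);
  }
private:
  CSParams p_;
  CSState s_;
  double h_;
};

// [[Rcpp::export(name = ".cs_plant_new_cpp")]]
SEXP cs_plant_new_cpp(List params, NumericVector state0, double h) {
  CSParams p = as_cs_params(params);
  CSState s;
  s.V = state0[0]; s.m = state0[1]; s.h = state0[2];
  s.n = state0[3]; s.a = state0[4]; s.b = state0[5];
  XPtr<CSPlant> ptr(new CSPlant(p, s, h), true);
  return ptr;
}

// [[Rcpp::export(name = ".cs_plant_step_cpp")]]
double cs_plant_step_cpp(SEXP plant, double i_inj, NumericVector i_noise) {
  XPtr<CSPlant> ptr(plant);
  return ptr->step(i_inj, i_noise);
}

// [[Rcpp::export(name = ".cs_plant_voltage_cpp")]]
double cs_plant_voltage_cpp(SEXP plant) {
  XPtr<CSPlant> ptr(plant);
  return ptr->voltage();
}

// [[Rcpp::export(name = ".cs_plant_state_cpp")]]
NumericVector cs_plant_state_cpp(SEXP plant) {
  XPtr<CSPlant> ptr(plant);
  return ptr->state();
}
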