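#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Receding-horizon optimizer for the RBFN voltage-increment model.
//
// Decision variables u[0..T-1] are the injected currents I_1..I_T; I_0 is the
// previously applied input. Dynamics constraint (embedded in the rollout):
//   V_{k+1} = V_k + sum_c w_c exp(-R ||S_k - mu_c||^2) + alpha (I_{k+1} + I_k)
// with S_k assembled from the measured history (k <= 0) and the model's own
// predictions (k > 0). Cost:
//   J = s e_T^2 + sum_{n=0}^{T-1} [ q e_{n+1}^2 + r (I_{n+1} - I_n)^2 ]
// subject to |I_n| <= i_max, solved by spectral projected gradient with
// analytic gradients and Armijo backtracking along the projection arc.

struct MPCProblem {
  const NumericMatrix& centers;
  const NumericVector& w;
  double alpha, R;
  int De, tau, T;
  const NumericVector& hist;   // measured voltages, most recent last
  double i_prev;
  const NumericVector& ref;    // ref[0..T-1] = Vref_{1..T}
  double s, q, r, i_max;

  double past_v(const std::vector<double>& Vp, int idx) const {
    // idx is the absolute prediction index; idx <= 0 reads history
    if (idx >= 0) return Vp[idx];
    return hist[hist.size() - 1 + idx];
  }

  // cost and (optionally) gradient
  double eval(const std::vector<double>& u, std::vector<double>* grad) const {
    int N = centers.nrow();
    std::vector<double> Vp(T + 1);
    Vp[0] = hist[hist.size() - 1];
    // dV[k][j] = dV_k/du_j, stored row-major
    std::vector<double> dV;
    if (grad) dV.assign((T + 1) * T, 0.0);

    std::vector<double> psi(N), Gd(De);
    for (int k = 0; k < T; ++k) {
      double F = 0.0;
      for (int d = 0; d < De; ++d) Gd[d] = 0.0;
      for (int c = 0; c < N; ++c) {
        double acc = 0.0;
        for (int d = 0; d < De; ++d) {
          double diff = past_v(Vp, k - d * tau) - centers(c, d);
          acc += diff * diff;
        }
        double p = w[c] * std::exp(-R * acc);
        F += p;
        if (grad) {
          for (int d = 0; d < De; ++d) {
            double diff = past_v(Vp, k - d * tau) - centers(c, d);
            Gd[d] += p * (-2.0 * R * diff);
          }
        }
      }
      double Ik  = (k == 0) ? i_prev : u[k - 1];
      double Ik1 = u[k];
      Vp[k + 1] = Vp[k] + F + alpha * (Ik1 + Ik);
      if (!std::isfinite(Vp[k + 1])) return R_PosInf;
      if (grad) {
        for (int j = 0; j < T; ++j) {
          double g = dV[k * T + j];
          for (int d = 0; d < De; ++d) {
            int idx = k - d * tau;
            if (idx > 0) g += Gd[d] * dV[idx * T + j];
          }
          if (j == k) g += alpha;
          if (k >= 1 && j == k - 1) g += alpha;
          dV[(k + 1) * T + j] = g;
        }
      }
    }

    double J = 0.0;
    if (grad) std::fill(grad->begin(), grad->end(), 0.0);
    for (int n = 0; n < T; ++n) {
      double e = Vp[n + 1] - ref[n];
      double wgt = q + ((n == T - 1) ? s : 0.0);
      J += wgt * e * e;
      if (grad) {
        for (int j = 0; j < T; ++j)
          (*grad)[j] += 2.0 * wgt * e * dV[(n + 1) * T + j];
      }
      double Iprev_n = (n == 0) ? i_prev : u[n - 1];
      double dI = u[n] - Iprev_n;
      J += r * dI * dI;
      if (grad) {
        (*grad)[n] += 2.0 * r * dI;
        if (n >= 1) (*grad)[n - 1] -= 2.0 * r * dI;
      }
    }
    return J;
  }
};

static inline double clampd(double x, double lo, double hi) {
  return std::min(hi, std::max(lo, x));
}

// [[Rcpp::export(name = ".mpc_solve_cpp")]]
List mpc_solve_cpp(NumericMatrix centers, NumericVector w, double alpha,
                   double R, int De, int tau,
                   NumericVector hist, double i_prev, NumericVector ref,
                   double s, double q, double r, double i_max,
                   NumericVector warm, int max_iter, double tol) {
  int T = ref.size();
  MPCProblem prob{centers, w, alpha, R, De, tau, T, hist, i_prev, ref,
                  s, q, r, i_max};

  std::vector<double> u(T);
  for (int j = 0; j < T; ++j)
    u[j] = clampd(warm.size() == T ? warm[j] : i_prev, -i_max, i_max);

  std::vector<double> g(T), u_new(T), g_new(T);
  double J = prob.eval(u, &g);
  if (!std::isfinite(J)) {
    std::fill(u.begin(), u.end(), clampd(i_prev, -i_max, i_max));
    J = prob.eval(u, &g);
  }

  double step = 1.0;
  {
    double gmax = 0.0;
    for (int j = 0; j < T; ++j) gmax = std::max(gmax, std::fabs(g[j]));
    step = (gmax > 0.0) ? 1.0 / gmax : 1.0;
  }

  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    // projected-gradient stationarity check
    double pg = 0.0;
    for (int j = 0; j < T; ++j)
      pg = std::max(pg, std::fabs(clampd(u[j] - g[j], -i_max, i_max) - u[j]));
    if (pg < tol) { converged = true; break; }

    double t = clampd(step, 1e-12, 1e12);
    double J_new = R_PosInf;
    for (int bt = 0; bt < 60; ++bt) {
      double descent = 0.0;
      for (int j = 0; j < T; ++j) {
        u_new[j] = clampd(u[j] - t * g[j], -i_max, i_max);
        descent += g[j] * (u[j] - u_new[j]);
      }
      J_new = prob.eval(u_new, &g_new);
      if (std::isfinite(J_new) && J_new <= J - 1e-4 * descent) break;
      t *= 0.5;
    }
    if (!std::isfinite(J_new) || J_new > J) break;  // line search failed

    // Barzilai-Borwein step for next iteration
    double sty = 0.0, sts = 0.0;
    for (int j = 0; j < T; ++j) {
      double sj = u_new[j] - u[j];
      double yj = g_new[j] - g[j];
      sts += sj * sj;
      sty += sj * yj;
    }
    step = (sty > 0.0) ? sts / sty : step * 2.0;

    u.swap(u_new);
    g.swap(g_new);
    J = J_new;
  }

  // dominance guard: never worse than holding the previous input
  std::vector<double> u_hold(T, clampd(i_prev, -i_max, i_max));
  double J_hold = prob.eval(u_hold, nullptr);
  if (!(J <= J_hold)) {
    u = u_hold;
    J = J_hold;
  }

  NumericVector out(T);
  for (int j = 0; j < T; ++j) out[j] = u[j];
  return List::create(_["input"] = out, _["cost"] = J,
                      _["converged"] = converged, _["iterations"] = it,
                      _["cost_hold"] = J_hold);
}
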