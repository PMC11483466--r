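#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian RBF activations: psi_c(S) = exp(-R * ||S - mu_c||^2)

// [[Rcpp::export(name = ".rbf_design_cpp")]]
NumericMatrix rbf_design_cpp(NumericMatrix states, NumericMatrix centers, double R) {
  int M = states.nrow(), N = centers.nrow(), D = states.ncol();
  if (centers.ncol() != D) stop("state and center dimensions differ");
  NumericMatrix out(M, N);
  for (int i = 0; i < M; ++i) {
    for (int c = 0; c < N; ++c) {
      double acc = 0.0;
      for (int d = 0; d < D; ++d) {
        double diff = states(i, d) - centers(c, d);
        acc += diff * diff;
      }
      out(i, c) = std::exp(-R * acc);
    }
  }
  return out;
}

// Open-loop rollout of the voltage-increment map
//   V[n+1] = V[n] + sum_c w_c psi_c(S_n) + alpha * (I[n+1] + I[n])
// with S_n built from the model's own past predictions after the seed.
// v_seed supplies samples V[0..L-1], L = (De-1)*tau + 1; the rollout starts
// at n = L-1 and runs to the end of the current vector i (aligned with V).

// [[Rcpp::export(name = ".ddf_forecast_cpp")]]
List ddf_forecast_cpp(NumericMatrix centers, NumericVector w, double alpha,
                      double R, int De, int tau,
                      NumericVector v_seed, NumericVector i,
                      double guard) {
  int N = centers.nrow();
  int L = (De - 1) * tau + 1;
  if (v_seed.size() != L) stop("seed must have exactly (De-1)*tau + 1 samples");
  int T = i.size();
  if (T < L) stop("current trace shorter than the seed");

  NumericVector V(T);
  for (int k = 0; k < L; ++k) V[k] = v_seed[k];
  bool diverged = false;
  int n_valid = T;

  for (int n = L - 1; n + 1 < T; ++n) {
    double F = 0.0;
    for (int c = 0; c < N; ++c) {
      double acc = 0.0;
      for (int d = 0; d < De; ++d) {
        double diff = V[n - d * tau] - centers(c, d);
        acc += diff * diff;
      }
      F += w[c] * std::exp(-R * acc);
    }
    double vnext = V[n] + F + alpha * (i[n + 1] + i[n]);
    if (!std::isfinite(vnext) || std::fabs(vnext) > guard) {
      diverged = true;
      n_valid = n + 1;
      break;
    }
    V[n + 1] = vnext;
  }
  return List::create(_["v"] = V, _["diverged"] = diverged, _["n_valid"] = n_valid);
}
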