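// Monte-Carlo ground-state searchers for the higher-order Ising energy
//   E(s) = -sum_{i<j} J_ij s_i s_j - sum_i h_i s_i + sum_{i<j<k} K_ijk s_i s_j s_k
// Both samplers draw randomness from R's RNG stream, so set.seed() on the
// R side makes them fully deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-spin adjacency of third-order terms for O(deg) flip deltas.
struct Triples {
  std::vector<std::vector<int>> by_spin;  // row ids of Kt touching spin i
  NumericMatrix Kt;                       // columns: i, j, k, value (1-based)
  Triples(const NumericMatrix& Kt_, int m) : Kt(Kt_) {
    by_spin.assign(m, {});
    for (int r = 0; r < Kt.nrow(); ++r) {
      by_spin[(int)Kt(r, 0) - 1].push_back(r);
      by_spin[(int)Kt(r, 1) - 1].push_back(r);
      by_spin[(int)Kt(r, 2) - 1].push_back(r);
    }
  }
};

static double full_energy(const std::vector<int>& s, const NumericVector& h,
                          const NumericMatrix& Jm, const NumericMatrix& Kt) {
  int m = s.size();
  double e = 0.0;
  for (int i = 0; i < m; ++i) {
    e -= h[i] * s[i];
    for (int j = i + 1; j < m; ++j) e -= Jm(i, j) * s[i] * s[j];
  }
  for (int r = 0; r < Kt.nrow(); ++r)
    e += Kt(r, 3) * s[(int)Kt(r, 0) - 1] * s[(int)Kt(r, 1) - 1] *
         s[(int)Kt(r, 2) - 1];
  return e;
}

// Energy change from flipping spin i: terms containing s_i change sign.
static double flip_delta(const std::vector<int>& s, int i,
                         const NumericVector& h, const NumericMatrix& Jm,
                         const Triples& tr) {
  int m = s.size();
  double field = h[i];
  for (int j = 0; j < m; ++j)
    if (j != i) field += Jm(i, j) * s[j];
  double d = 2.0 * s[i] * field;
  double ksum = 0.0;
  for (int r : tr.by_spin[i]) {
    int a = (int)tr.Kt(r, 0) - 1, b = (int)tr.Kt(r, 1) - 1,
        c = (int)tr.Kt(r, 2) - 1;
    ksum += tr.Kt(r, 3) * s[a] * s[b] * s[c];
  }
  d -= 2.0 * ksum;
  return d;
}

// [[Rcpp::export]]
List anneal_sa_cpp(NumericVector h, NumericMatrix Jm, NumericMatrix Kt,
                   int n_sweeps, double t_start, double t_end,
                   int n_restarts) {
  int m = h.size();
  Triples tr(Kt, m);
  double decay = std::pow(t_end / t_start, 1.0 / std::max(1, n_sweeps - 1));
  std::vector<int> best_s(m, 1);
  double best_e = R_PosInf;
  NumericVector best_trace(n_sweeps);
  for (int rs = 0; rs < n_restarts; ++rs) {
    std::vector<int> s(m);
    for (int i = 0; i < m; ++i) s[i] = unif_rand() < 0.5 ? 1 : -1;
    double e = full_energy(s, h, Jm, Kt);
    std::vector<int> loc_best = s;
    double loc_e = e;
    NumericVector trace(n_sweeps);
    double T = t_start;
    for (int sw = 0; sw < n_sweeps; ++sw) {
      for (int i = 0; i < m; ++i) {
        double d = flip_delta(s, i, h, Jm, tr);
        if (d <= 0.0 || unif_rand() < std::exp(-d / T)) {
          s[i] = -s[i];
          e += d;
          if (e < loc_e) { loc_e = e; loc_best = s; }
        }
      }
      trace[sw] = loc_e;
      T *= decay;
    }
    if (loc_e < best_e) {
      best_e = loc_e;
      best_s = loc_best;
      best_trace = trace;
    }
  }
  return List::create(_["configuration"] = IntegerVector(best_s.begin(), best_s.end()),
                      _["energy"] = best_e, _["trace"] = best_trace);
}

// [[Rcpp::export]]
List anneal_sqa_cpp(NumericVector h, NumericMatrix Jm, NumericMatrix Kt,
                    int n_sweeps, double temperature,
                    double gamma_start, double gamma_end,
                    int n_trotter, int n_restarts) {
  if (gamma_start <= 0.0 || gamma_end <= 0.0)
    stop("transverse field must be positive");
  int m = h.size(), P = n_trotter;
  Triples tr(Kt, m);
  double T = temperature;
  double decay = std::pow(gamma_end / gamma_start,
                          1.0 / std::max(1, n_sweeps - 1));
  std::vector<int> best_s(m, 1);
  double best_e = R_PosInf;
  NumericVector best_trace(n_sweeps);
  for (int rs = 0; rs < n_restarts; ++rs) {
    // replicas[p] is one Trotter slice
    std::vector<std::vector<int>> rep(P, std::vector<int>(m));
    std::vector<double> rep_e(P);
    for (int p = 0; p < P; ++p) {
      for (int i = 0; i < m; ++i) rep[p][i] = unif_rand() < 0.5 ? 1 : -1;
      rep_e[p] = full_energy(rep[p], h, Jm, Kt);
    }
    std::vector<int> loc_best(m);
    double loc_e = R_PosInf;
    for (int p = 0; p < P; ++p)
      if (rep_e[p] < loc_e) { loc_e = rep_e[p]; loc_best = rep[p]; }
    NumericVector trace(n_sweeps);
    double gamma = gamma_start;
    for (int sw = 0; sw < n_sweeps; ++sw) {
      double jperp = -0.5 * std::log(std::tanh(gamma / (P * T)));
      for (int p = 0; p < P; ++p) {
        int up = (p + 1) % P, dn = (p + P - 1) % P;
        for (int i = 0; i < m; ++i) {
          double d_prob = flip_delta(rep[p], i, h, Jm, tr);
          double d_coup = 2.0 * jperp * rep[p][i] *
                          (rep[up][i] + rep[dn][i]);
          double d = d_prob / P + d_coup;
          if (d <= 0.0 || unif_rand() < std::exp(-d / T)) {
            rep[p][i] = -rep[p][i];
            rep_e[p] += d_prob;
            if (rep_e[p] < loc_e) { loc_e = rep_e[p]; loc_best = rep[p]; }
          }
        }
      }
      trace[sw] = loc_e;
      gamma *= decay;
    }
    if (loc_e < best_e) {
      best_e = loc_e;
      best_s = loc_best;
      best_trace = trace;
    }
  }
  return List::create(_["configuration"] = IntegerVector(best_s.begin(), best_s.end()),
                      _["energy"] = best_e, _["trace"] = best_trace);
}
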