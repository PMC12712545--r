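#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Simulated-annealing reserve selection with incremental objective
// updates. Objective = sum(cost of selected) + blm * exposed boundary of
// the selected set + sum_f spf_f * base_f * max(0, (T_f - held_f)/T_f).
// Locked (reserved) units are forced selected and never flipped.
// Randomness comes from R's RNG (seed via set.seed in the caller).
// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericVector cost, NumericVector outer_len,
                IntegerVector edge_i, IntegerVector edge_j,
                NumericVector edge_len, NumericMatrix amounts,
                NumericVector target, NumericVector spf,
                NumericVector base_penalty, LogicalVector locked,
                double blm, int iterations, double cooling,
                double init_select_prob) {
  int n = cost.size(), nf = target.size(), ne = edge_i.size();
  RNGScope scope;

  // adjacency lists
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (int e = 0; e < ne; ++e) {
    adj[edge_i[e]].push_back({edge_j[e], edge_len[e]});
    adj[edge_j[e]].push_back({edge_i[e], edge_len[e]});
  }

  std::vector<int> sel(n, 0);
  for (int u = 0; u < n; ++u)
    sel[u] = locked[u] ? 1 : (unif_rand() < init_select_prob ? 1 : 0);

  std::vector<double> held(nf, 0.0);
  for (int u = 0; u < n; ++u)
    if (sel[u]) for (int f = 0; f < nf; ++f) held[f] += amounts(u, f);

  auto penalty_f = [&](int f, double h) {
    if (target[f] <= 0) return 0.0;
    double short_frac = (target[f] - h) / target[f];
    if (short_frac <= 0) return 0.0;
    return spf[f] * base_penalty[f] * short_frac;
  };

  // delta objective of flipping u
  auto delta_of = [&](int u) {
    int s = sel[u];
    double sign = s ? -1.0 : 1.0;
    double d = sign * cost[u];
    double db = sign * outer_len[u];
    for (auto &pr : adj[u]) {
      int xo = sel[u] ^ sel[pr.first];
      db += pr.second * (xo ? -1.0 : 1.0);
    }
    d += blm * db;
    for (int f = 0; f < nf; ++f) {
      double a = amounts(u, f);
      if (a == 0.0) continue;
      double h_new = held[f] + sign * a;
      d += penalty_f(f, h_new) - penalty_f(f, held[f]);
    }
    return d;
  };

  auto apply_flip = [&](int u) {
    double sign = sel[u] ? -1.0 : 1.0;
    for (int f = 0; f < nf; ++f) held[f] += sign * amounts(u, f);
    sel[u] = 1 - sel[u];
  };

  std::vector<int> free_units;
  for (int u = 0; u < n; ++u) if (!locked[u]) free_units.push_back(u);
  int nfree = free_units.size();
  if (nfree == 0) iterations = 0;

  // auto temperature: 90th percentile of |delta| over 100 random probes
  double T = 1.0;
  if (nfree > 0) {
    std::vector<double> probes;
    for (int p = 0; p < 100; ++p) {
      int u = free_units[(int)(unif_rand() * nfree) % nfree];
      probes.push_back(std::fabs(delta_of(u)));
    }
    std::sort(probes.begin(), probes.end());
    T = probes[(int)(0.9 * (probes.size() - 1))];
    if (T <= 0) T = 1.0;
  }
  double T0 = T;

  for (int it = 0; it < iterations; ++it) {
    int u = free_units[(int)(unif_rand() * nfree) % nfree];
    double d = delta_of(u);
    if (d <= 0 || unif_rand() < std::exp(-d / T)) apply_flip(u);
    T *= cooling;
    if (T < 1e-12) T = 1e-12;
  }

  // greedy descent to a local optimum
  bool improved = true;
  while (improved) {
    improved = false;
    for (int k = 0; k < nfree; ++k) {
      int u = free_units[k];
      if (delta_of(u) < -1e-12) { apply_flip(u); improved = true; }
    }
  }

  // exact final objective
  double c_term = 0.0, b_term = 0.0, p_term = 0.0;
  for (int u = 0; u < n; ++u) if (sel[u]) {
    c_term += cost[u];
    b_term += outer_len[u];
  }
  for (int e = 0; e < ne; ++e)
    if (sel[edge_i[e]] != sel[edge_j[e]]) b_term += edge_len[e];
  for (int f = 0; f < nf; ++f) p_term += penalty_f(f, held[f]);

  LogicalVector out(n);
  for (int u = 0; u < n; ++u) out[u] = sel[u] == 1;
  return List::create(_["selection"] = out,
                      _["value"] = c_term + blm * b_term + p_term,
                      _["cost_term"] = c_term,
                      _["boundary_length"] = b_term,
                      _["boundary_term"] = blm * b_term,
                      _["penalty_term"] = p_term,
                      _["initial_temperature"] = T0);
}
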