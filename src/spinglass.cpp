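#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-node-move simulated annealing for the spin-glass Hamiltonian
//   H(sigma) = - sum_{i<j} (A_ij - gamma * k_i k_j / 2m) * delta(sigma_i, sigma_j)
// with geometric cooling. Uses R's RNG so seeds flow from set.seed() in R.
//
// adj / adj_start: 0-based CSR adjacency (neighbours of node i are
// adj[adj_start[i] .. adj_start[i+1]-1]).

static double links_to(const IntegerVector& adj, const IntegerVector& start,
                       const IntegerVector& spin, int i, int s) {
  int cnt = 0;
  for (int e = start[i]; e < start[i + 1]; ++e)
    if (spin[adj[e]] == s) ++cnt;
  return (double)cnt;
}

// [[Rcpp::export(name = ".spinglass_anneal_cpp")]]
List spinglass_anneal_cpp(IntegerVector adj, IntegerVector adj_start,
                          NumericVector deg, int q, double gamma,
                          double t0, double cooling, double tmin) {
  int n = adj_start.size() - 1;
  double two_m = 0.0;
  for (int i = 0; i < n; ++i) two_m += deg[i];

  IntegerVector spin(n);
  for (int i = 0; i < n; ++i)
    spin[i] = (int)std::floor(unif_rand() * q);

  // degree mass per spin
  std::vector<double> K(q, 0.0);
  for (int i = 0; i < n; ++i) K[spin[i]] += deg[i];

  // current H
  double H = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int e = adj_start[i]; e < adj_start[i + 1]; ++e) {
      int j = adj[e];
      if (j > i && spin[j] == spin[i]) H -= 1.0;
    }
  }
  for (int s = 0; s < q; ++s) H += gamma * K[s] * K[s] / (2.0 * two_m);
  // subtract the i == j "pair" terms included above: H null-model part is
  // sum_{i<j, same spin} gamma k_i k_j / 2m = (sum_s K_s^2 - sum_i k_i^2) / (2 * 2m) * gamma
  double sumk2 = 0.0;
  for (int i = 0; i < n; ++i) sumk2 += deg[i] * deg[i];
  H -= gamma * sumk2 / (2.0 * two_m);

  // auto temperature: median-ish |dH| of random proposals
  double T = t0;
  if (t0 <= 0.0) {
    double acc = 0.0; int m = 0;
    for (int t = 0; t < 200; ++t) {
      int i = (int)std::floor(unif_rand() * n);
      int s = spin[i];
      int snew = (int)std::floor(unif_rand() * q);
      if (snew == s) continue;
      double dH = -(links_to(adj, adj_start, spin, i, snew) -
                    links_to(adj, adj_start, spin, i, s)) +
        gamma * deg[i] * (K[snew] - (K[s] - deg[i])) / two_m;
      acc += std::fabs(dH); ++m;
    }
    T = (m > 0 && acc > 0) ? (acc / m) / std::log(2.0) : 1.0;
  }

  IntegerVector best = clone(spin);
  double bestH = H;

  bool any_accept = true;
  int sweeps = 0;
  const int max_sweeps = 20000;  // hard safety cap
  while ((T >= tmin || any_accept) && sweeps < max_sweeps) {
    ++sweeps;
    any_accept = false;
    for (int t = 0; t < n; ++t) {
      int i = (int)std::floor(unif_rand() * n);
      int s = spin[i];
      int snew = (int)std::floor(unif_rand() * q);
      if (snew == s) continue;
      double dH = -(links_to(adj, adj_start, spin, i, snew) -
                    links_to(adj, adj_start, spin, i, s)) +
        gamma * deg[i] * (K[snew] - (K[s] - deg[i])) / two_m;
      if (dH <= 0.0 || (T > 0 && unif_rand() < std::exp(-dH / T))) {
        spin[i] = snew;
        K[s] -= deg[i];
        K[snew] += deg[i];
        H += dH;
        // zero-cost shuffles do not count as progress, so cooling can stop
        if (std::fabs(dH) > 1e-12) any_accept = true;
        if (H < bestH - 1e-12) { bestH = H; best = clone(spin); }
      }
    }
    T *= cooling;
    if (T < tmin && !any_accept) break;
  }

  // greedy polish from the best configuration: move each node to its best
  // spin until no single-node move improves H
  spin = clone(best);
  for (int s = 0; s < q; ++s) K[s] = 0.0;
  for (int i = 0; i < n; ++i) K[spin[i]] += deg[i];
  H = bestH;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 0; i < n; ++i) {
      int s = spin[i];
      double l_s = links_to(adj, adj_start, spin, i, s);
      double bestd = 0.0; int bests = s;
      for (int c = 0; c < q; ++c) {
        if (c == s) continue;
        double dH = -(links_to(adj, adj_start, spin, i, c) - l_s) +
          gamma * deg[i] * (K[c] - (K[s] - deg[i])) / two_m;
        if (dH < bestd - 1e-12) { bestd = dH; bests = c; }
      }
      if (bests != s) {
        spin[i] = bests;
        K[s] -= deg[i];
        K[bests] += deg[i];
        H += bestd;
        improved = true;
      }
    }
  }

  return List::create(_["spin"] = spin, _["H"] = H);
}
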