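#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis equilibration of the epigenetic (telophase) lattice.
//
// Under a fixed protein environment the Hamiltonian is a sum of
// single-site terms: E(S) = sum_i h[i]*S_i + c[i]*|S_i| with
// S_i in {-1, 0, +1}. h collects the rule 1/2/4 linear fields, c the
// rule 3 bivalence penalty. Sites are initialized uniformly at random,
// a move proposes one of the two alternative values with equal
// probability, and is accepted with probability min[1, exp(-beta*dE)].
// Averages are accumulated over the second half of the updates
// (first half burn-in); the convergence flag compares the 3rd and 4th
// quarter running averages (max drift < tol).
//
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
List mc_ternary_field(NumericVector h, NumericVector c, double beta,
                      int updates, double tol = 0.15) {
  int n = h.size();
  if (n < 1) stop("empty lattice");
  if (c.size() != n) stop("h and c must have equal length");
  if (updates < 4) stop("updates_per_phase must be at least 4");
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(h[i]) || !std::isfinite(c[i]))
      stop("non-finite field");

  std::vector<int> S(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    S[i] = (u < 1.0 / 3.0) ? -1 : ((u < 2.0 / 3.0) ? 0 : 1);
  }

  int half = updates / 2;
  int q3_end = half + (updates - half) / 2;
  std::vector<double> sum3(n, 0.0), sum4(n, 0.0);
  long n3 = 0, n4 = 0;

  for (int t = 0; t < updates; ++t) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    int s = S[i];
    int alt1, alt2;
    if (s == -1)      { alt1 = 0;  alt2 = 1; }
    else if (s == 0)  { alt1 = -1; alt2 = 1; }
    else              { alt1 = -1; alt2 = 0; }
    int sp = (unif_rand() < 0.5) ? alt1 : alt2;
    double dE = h[i] * (sp - s) + c[i] * (std::abs(sp) - std::abs(s));
    if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) S[i] = sp;
    if (t >= half) {
      if (t < q3_end) {
        for (int j = 0; j < n; ++j) sum3[j] += S[j];
        ++n3;
      } else {
        for (int j = 0; j < n; ++j) sum4[j] += S[j];
        ++n4;
      }
    }
  }

  NumericVector avg(n);
  double drift = 0.0;
  for (int i = 0; i < n; ++i) {
    double a3 = sum3[i] / n3, a4 = sum4[i] / n4;
    avg[i] = (sum3[i] + sum4[i]) / (double)(n3 + n4);
    double d = std::fabs(a3 - a4);
    if (d > drift) drift = d;
  }
  return List::create(_["avg"] = avg, _["converged"] = (drift < tol),
                      _["drift"] = drift, _["updates"] = updates);
}

// Metropolis equilibration of the expression (interphase) lattice.
//
// Sites are binary spins S in {0,1}, grouped into modules. The
// Hamiltonian is E(S) = sum_i f[i]*S_i + J * sum_{(m,m') in pairs}
// P_m * P_m', where P_m is the product of the spins of module m (all
// genes expressed). With one gene per module this is the base-model
// mutual-repression term between nearest-neighbour modules.
//
// module_of_site: 0-based module index per site; pairs: 2-column
// 0-based matrix of coupled module pairs (each pair once).
// [[Rcpp::export]]
List mc_ising_modules(NumericVector f, IntegerVector module_of_site,
                      int n_modules, IntegerMatrix pairs, double J,
                      double beta, int updates, double tol = 0.15) {
  int n = f.size();
  if (n < 1) stop("empty lattice");
  if (module_of_site.size() != n) stop("module_of_site size mismatch");
  if (updates < 4) stop("updates_per_phase must be at least 4");
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(f[i])) stop("non-finite field");

  // module adjacency from pairs
  std::vector<std::vector<int>> nb(n_modules);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int a = pairs(p, 0), b = pairs(p, 1);
    if (a < 0 || a >= n_modules || b < 0 || b >= n_modules)
      stop("pair index out of range");
    nb[a].push_back(b);
    nb[b].push_back(a);
  }

  std::vector<int> S(n);
  std::vector<int> zero_count(n_modules, 0);
  for (int i = 0; i < n; ++i) {
    S[i] = (unif_rand() < 0.5) ? 0 : 1;
    if (S[i] == 0) zero_count[module_of_site[i]]++;
  }

  int half = updates / 2;
  int q3_end = half + (updates - half) / 2;
  std::vector<double> sum3(n, 0.0), sum4(n, 0.0);
  long n3 = 0, n4 = 0;

  for (int t = 0; t < updates; ++t) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    int m = module_of_site[i];
    int s = S[i], sp = 1 - s;
    double dE = f[i] * (sp - s);
    // module product changes only if every other gene in m is expressed
    int others_zero = zero_count[m] - (s == 0 ? 1 : 0);
    if (others_zero == 0) {
      double nb_on = 0.0;
      for (size_t k = 0; k < nb[m].size(); ++k)
        if (zero_count[nb[m][k]] == 0) nb_on += 1.0;
      dE += J * (sp - s) * nb_on;
    }
    if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
      S[i] = sp;
      zero_count[m] += (sp == 0) ? 1 : -1;
    }
    if (t >= half) {
      if (t < q3_end) {
        for (int j = 0; j < n; ++j) sum3[j] += S[j];
        ++n3;
      } else {
        for (int j = 0; j < n; ++j) sum4[j] += S[j];
        ++n4;
      }
    }
  }

  NumericVector avg(n);
  double drift = 0.0;
  for (int i = 0; i < n; ++i) {
    double a3 = sum3[i] / n3, a4 = sum4[i] / n4;
    avg[i] = (sum3[i] + sum4[i]) / (double)(n3 + n4);
    double d = std::fabs(a3 - a4);
    if (d > drift) drift = d;
  }
  return List::create(_["avg"] = avg, _["converged"] = (drift < tol),
                      _["drift"] = drift, _["updates"] = updates);
}
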