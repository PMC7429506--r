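#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Simulated annealing over assignments for one guild of a network alignment.
// State: a permutation perm with row i (species of network A, possibly padded
// with dummies) assigned to column perm[i] (species of network B, possibly
// padded). D[i,j] holds the pair cost 1 - c_ij; dummy rows/columns cost 0.
// Moves swap the partners of two rows; frozen rows (fixed pairs) never move.
// Best strictly-improving state is retained and polished by greedy descent.

namespace {

double perm_cost(const NumericMatrix &D, const std::vector<int> &perm) {
  double c = 0.0;
  for (size_t i = 0; i < perm.size(); ++i) c += D(i, perm[i]);
  return c;
}

void greedy_descent(const NumericMatrix &D, std::vector<int> &perm,
                    const std::vector<int> &mov) {
  const size_t nm = mov.size();
  bool improved = true;
  while (improved) {
    improved = false;
    for (size_t x = 0; x + 1 < nm; ++x)
      for (size_t y = x + 1; y < nm; ++y) {
        int i = mov[x], j = mov[y];
        double d = D(i, perm[j]) + D(j, perm[i]) - D(i, perm[i]) - D(j, perm[j]);
        if (d < -1e-12) {
          std::swap(perm[i], perm[j]);
          improved = true;
        }
      }
  }
}

} // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericMatrix D, IntegerVector init, LogicalVector frozen,
                int sweeps, double t0, double cooling, double seed) {
  const int m = D.nrow();
  std::vector<int> perm(init.begin(), init.end());
  std::vector<int> mov;
  for (int i = 0; i < m; ++i) if (!frozen[i]) mov.push_back(i);

  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // random initial assignment of the movable rows (Fisher-Yates on their columns)
  for (size_t i = mov.size(); i > 1; --i) {
    size_t j = (size_t)(unif(rng) * i);
    if (j >= i) j = i - 1;
    std::swap(perm[mov[i - 1]], perm[mov[j]]);
  }

  double cost = perm_cost(D, perm);
  std::vector<int> best_perm = perm;
  double best_cost = cost;

  if (mov.size() >= 2) {
    const size_t nm = mov.size();
    double T = t0;
    for (int s = 0; s < sweeps; ++s) {
      for (size_t k = 0; k < nm; ++k) {
        size_t x = (size_t)(unif(rng) * nm); if (x >= nm) x = nm - 1;
        size_t y = (size_t)(unif(rng) * (nm - 1)); if (y >= nm - 1) y = nm - 2;
        if (y >= x) ++y;
        int i = mov[x], j = mov[y];
        double d = D(i, perm[j]) + D(j, perm[i]) - D(i, perm[i]) - D(j, perm[j]);
        if (d < 0.0 || unif(rng) < std::exp(-d / T)) {
          std::swap(perm[i], perm[j]);
          cost += d;
          if (cost < best_cost - 1e-12) { best_cost = cost; best_perm = perm; }
        }
      }
      T *= cooling;
    }
    greedy_descent(D, best_perm, mov);
    best_cost = perm_cost(D, best_perm);
  }

  return List::create(_["perm"] = IntegerVector(best_perm.begin(), best_perm.end()),
                      _["cost"] = best_cost);
}
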