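#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-energy nested secondary structure by interval dynamic programming,
// with a simplified per-pair energy model (no loop terms, no stacking).
// Tie-breaks: among equal-energy structures prefer the one with more pairs,
// then the one whose pairs sit 5'-most. Pseudoknot-free by construction;
// hairpin loops must span at least `minloop` unpaired bases.

static inline double pair_energy(char a, char b,
                                 double e_gc, double e_au, double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 1.0; // sentinel: not pairable
}

// Compare (energy, -npairs): returns true if (e1,p1) strictly better.
static inline bool better(double e1, int p1, double e2, int p2) {
  const double eps = 1e-9;
  if (e1 < e2 - eps) return true;
  if (e1 > e2 + eps) return false;
  return p1 > p2;
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, double e_gc, double e_au, double e_gu,
                       int minloop) {
  int n = seq.size();
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, 0));

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // option: j unpaired
      double bestE = E[i][j - 1];
      int bestP = P[i][j - 1];
      // option: pair (k, j), k in [i, j - minloop - 1]
      for (int k = i; k <= j - minloop - 1; ++k) {
        double pe = pair_energy(seq[k], seq[j], e_gc, e_au, e_gu);
        if (pe > 0) continue;
        double e = pe;
        int p = 1;
        if (k > i) { e += E[i][k - 1]; p += P[i][k - 1]; }
        if (k + 1 <= j - 1) { e += E[k + 1][j - 1]; p += P[k + 1][j - 1]; }
        if (better(e, p, bestE, bestP)) { bestE = e; bestP = p; }
      }
      E[i][j] = bestE;
      P[i][j] = bestP;
    }
  }

  // traceback: scan pairing options 5'-most first so ties resolve towards
  // the 5' end; stack of intervals.
  std::vector<int> partner(n, 0); // 1-based partner, 0 = unpaired
  std::vector<std::pair<int, int> > stack;
  if (n >= 2) stack.push_back(std::make_pair(0, n - 1));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 1) continue;
    double target = E[i][j];
    int targetP = P[i][j];
    bool placed = false;
    for (int k = i; k <= j - minloop - 1 && !placed; ++k) {
      double pe = pair_energy(seq[k], seq[j], e_gc, e_au, e_gu);
      if (pe > 0) continue;
      double e = pe;
      int p = 1;
      if (k > i) { e += E[i][k - 1]; p += P[i][k - 1]; }
      if (k + 1 <= j - 1) { e += E[k + 1][j - 1]; p += P[k + 1][j - 1]; }
      if (std::abs(e - target) <= eps && p == targetP) {
        partner[k] = j + 1;
        partner[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        placed = true;
      }
    }
    if (!placed) {
      // j is unpaired in the optimum
      stack.push_back(std::make_pair(i, j - 1));
    }
  }

  std::string structure(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > 0) structure[i] = (partner[i] - 1 > i) ? '(' : ')';
  }
  double mfe = (n >= 2) ? E[0][n - 1] : 0.0;
  return List::create(_["structure"] = structure,
                      _["mfe"] = mfe,
                      _["pair_table"] = IntegerVector(partner.begin(), partner.end()));
}
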