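#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Miller-Madow entropy from a count vector: plugin entropy + (m-1)/(2n),
// m = number of occupied cells, natural-log units.
static double entropy_mm(const std::vector<int>& counts, int n) {
  double h = 0.0;
  int occupied = 0;
  for (size_t i = 0; i < counts.size(); ++i) {
    int c = counts[i];
    if (c > 0) {
      double p = (double)c / n;
      h -= p * std::log(p);
      ++occupied;
    }
  }
  return h + (occupied - 1) / (2.0 * n);
}

// All-pairs Miller-Madow mutual information on a cells x genes matrix of
// 0-based bin indices. Returns a symmetric genes x genes matrix (diagonal 0).
// [[Rcpp::export]]
NumericMatrix cpp_mi_matrix(const IntegerMatrix& bins, int B) {
  const int n = bins.nrow(), g = bins.ncol();
  NumericMatrix mi(g, g);
  // marginal entropies
  std::vector<double> hmarg(g);
  for (int j = 0; j < g; ++j) {
    std::vector<int> cnt(B, 0);
    for (int i = 0; i < n; ++i) cnt[bins(i, j)]++;
    hmarg[j] = entropy_mm(cnt, n);
  }
  std::vector<int> joint(B * B);
  for (int a = 0; a < g; ++a) {
    for (int b = a + 1; b < g; ++b) {
      std::fill(joint.begin(), joint.end(), 0);
      for (int i = 0; i < n; ++i) joint[bins(i, a) * B + bins(i, b)]++;
      double hj = entropy_mm(joint, n);
      double v = hmarg[a] + hmarg[b] - hj;
      mi(a, b) = v;
      mi(b, a) = v;
    }
  }
  return mi;
}

// Data-processing-inequality pruning: an edge (i,j) (present iff mi > 0) is
// removed when some third gene k forms a triangle in which (i,j) is strictly
// the weakest edge by more than eps. Decisions are taken simultaneously on
// the input matrix, as in standard ARACNe.
// [[Rcpp::export]]
LogicalMatrix cpp_dpi_prune(const NumericMatrix& mi, double eps) {
  const int g = mi.nrow();
  LogicalMatrix keep(g, g);
  for (int i = 0; i < g; ++i)
    for (int j = i + 1; j < g; ++j) {
      bool k_ij = mi(i, j) > 0;
      if (k_ij && R_finite(eps)) {
        for (int k = 0; k < g; ++k) {
          if (k == i || k == j) continue;
          if (mi(i, k) > 0 && mi(j, k) > 0 &&
              mi(i, j) < mi(i, k) - eps && mi(i, j) < mi(j, k) - eps) {
            k_ij = false;
            break;
          }
        }
      }
      keep(i, j) = k_ij;
      keep(j, i) = k_ij;
    }
  return keep;
}
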