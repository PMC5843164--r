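#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cumulative DTW cost between two multivariate series held column-major as
// (n epochs x k channels) matrices. Local cost d(i,j) is the Euclidean norm
// of the difference of the channel vectors. Step patterns:
//   sym2: g(i,j) = min(g(i-1,j-1) + 2 d, g(i-1,j) + d, g(i,j-1) + d),
//         g(1,1) = 2 d(1,1)   (diagonal weight 2; normalizable by n+m)
//   sym1: as above with diagonal weight 1 and g(1,1) = d(1,1)
static double dtw_cost(const double* a, int na, const double* b, int nb,
                       int k, bool sym2) {
  const double wdiag = sym2 ? 2.0 : 1.0;
  std::vector<double> prev(nb), cur(nb), drow(nb);
  // local cost of row i against all j; channel-outer loops vectorize
  for (int i = 0; i < na; ++i) {
    {
      const double a0 = a[i];
      for (int j = 0; j < nb; ++j) {
        double diff = a0 - b[j];
        drow[j] = diff * diff;
      }
      for (int c = 1; c < k; ++c) {
        const double ac = a[i + (size_t)c * na];
        const double* bc = b + (size_t)c * nb;
        for (int j = 0; j < nb; ++j) {
          double diff = ac - bc[j];
          drow[j] += diff * diff;
        }
      }
      for (int j = 0; j < nb; ++j) drow[j] = std::sqrt(drow[j]);
    }
    if (i == 0) {
      cur[0] = wdiag * drow[0];
      for (int j = 1; j < nb; ++j) cur[j] = cur[j - 1] + drow[j];
    } else {
      cur[0] = prev[0] + drow[0];
      for (int j = 1; j < nb; ++j) {
        double best = prev[j - 1] + wdiag * drow[j];
        double up = prev[j] + drow[j];
        double left = cur[j - 1] + drow[j];
        if (up < best) best = up;
        if (left < best) best = left;
        cur[j] = best;
      }
    }
    std::swap(prev, cur);
  }
  return prev[nb - 1];
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b, bool sym2) {
  if (a.ncol() != b.ncol()) stop("channel count mismatch");
  return dtw_cost(a.begin(), a.nrow(), b.begin(), b.nrow(), a.ncol(), sym2);
}

// All-pairs DTW over a cube of equal-length series: `cube` is
// n_epochs x k channels x n_cycles (column-major). Returns the symmetric
// matrix of cumulative costs (each pair computed once).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericVector cube, int n_epochs, int k,
                               int n_cycles, bool sym2) {
  NumericMatrix out(n_cycles, n_cycles);
  const double* base = cube.begin();
  const size_t stride = (size_t)n_epochs * k;
  for (int i = 0; i < n_cycles; ++i) {
    for (int j = i + 1; j < n_cycles; ++j) {
      double c = dtw_cost(base + stride * i, n_epochs,
                          base + stride * j, n_epochs, k, sym2);
      out(i, j) = c;
      out(j, i) = c;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
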