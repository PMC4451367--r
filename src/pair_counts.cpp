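#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// first index (0-based) with g[idx] >= d, or g.size() if none;
// ties at d == eps count as within eps (Heaviside H(0) = 1)
static inline int grid_index(double d, const NumericVector &g) {
  int lo = 0, hi = g.size();
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (g[mid] >= d) hi = mid; else lo = mid + 1;
  }
  return lo;
}

static inline double pair_total(int nv, int theiler) {
  int k = nv - theiler;
  if (k < 2) return 0.0;
  return (double)k * (double)(k - 1) / 2.0;
}

// Template-matching pair counts at embedding dimensions m and m+1
// (Chebyshev distance, delay L), cumulative over an ascending eps grid.
// Both dimensions use the same nv = N - m*L templates (sample-entropy
// convention), so counts_m1[g] <= counts_m[g] holds exactly.
// theiler = minimum index separation minus 1 (0 means all distinct pairs).
// [[Rcpp::export]]
List pair_counts_dual(NumericVector x, int m, int L, NumericVector eps,
                      int theiler = 0) {
  const int n = x.size();
  const int nv = n - m * L;
  const int G = eps.size();
  if (m < 1 || L < 1) stop("m and L must be >= 1");
  if (nv < 2) stop("series too short for (m+1)-dimensional embedding");
  if (G < 1) stop("empty eps grid");
  for (int g = 0; g < G; ++g) {
    if (eps[g] <= 0) stop("eps values must be positive");
    if (g > 0 && eps[g] <= eps[g - 1]) stop("eps grid must be strictly ascending");
  }
  const double epsmax = eps[G - 1];
  std::vector<double> hist_m(G + 1, 0.0), hist_m1(G + 1, 0.0);

  for (int i = 0; i < nv - 1; ++i) {
    for (int j = i + 1 + theiler; j < nv; ++j) {
      double dm = 0.0;
      bool over = false;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k * L] - x[j + k * L]);
        if (d > dm) {
          dm = d;
          if (dm > epsmax) { over = true; break; }
        }
      }
      if (over) continue;
      hist_m[grid_index(dm, eps)] += 1.0;
      double d1 = std::fabs(x[i + m * L] - x[j + m * L]);
      double dm1 = (d1 > dm) ? d1 : dm;
      if (dm1 <= epsmax) hist_m1[grid_index(dm1, eps)] += 1.0;
    }
  }

  NumericVector cm(G), cm1(G);
  double s = 0.0, s1 = 0.0;
  for (int g = 0; g < G; ++g) {
    s += hist_m[g];   cm[g] = s;
    s1 += hist_m1[g]; cm1[g] = s1;
  }
  return List::create(_["counts_m"] = cm, _["counts_m1"] = cm1,
                      _["n_pairs"] = pair_total(nv, theiler),
                      _["n_vectors"] = nv);
}

// Pair counts at a single embedding dimension m over all
// nv = N - (m-1)*L delay vectors (the plain correlation-integral
// convention), cumulative over an ascending eps grid.
// [[Rcpp::export]]
List pair_counts_single(NumericVector x, int m, int L, NumericVector eps,
                        int theiler = 0) {
  const int n = x.size();
  const int nv = n - (m - 1) * L;
  const int G = eps.size();
  if (m < 1 || L < 1) stop("m and L must be >= 1");
  if (nv < 2) stop("series too short for m-dimensional embedding");
  if (G < 1) stop("empty eps grid");
  for (int g = 0; g < G; ++g) {
    if (eps[g] <= 0) stop("eps values must be positive");
    if (g > 0 && eps[g] <= eps[g - 1]) stop("eps grid must be strictly ascending");
  }
  const double epsmax = eps[G - 1];
  std::vector<double> hist(G + 1, 0.0);

  for (int i = 0; i < nv - 1; ++i) {
    for (int j = i + 1 + theiler; j < nv; ++j) {
      double dm = 0.0;
      bool over = false;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k * L] - x[j + k * L]);
        if (d > dm) {
          dm = d;
          if (dm > epsmax) { over = true; break; }
        }
      }
      if (over) continue;
      hist[grid_index(dm, eps)] += 1.0;
    }
  }

  NumericVector cm(G);
  double s = 0.0;
  for (int g = 0; g < G; ++g) { s += hist[g]; cm[g] = s; }
  return List::create(_["counts"] = cm,
                      _["n_pairs"] = pair_total(nv, theiler),
                      _["n_vectors"] = nv);
}
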