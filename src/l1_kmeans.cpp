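#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// L1 (cityblock) k-means kernel: nearest-centroid assignment under the L1
// metric and coordinate-wise median centroid updates. Kept in C++ because the
// window matrix is N x p(p-1)/2 and the assignment step is O(N*K*d) per
// iteration.

static double l1_dist(const NumericMatrix& X, int row,
                      const NumericMatrix& C, int crow, int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += std::fabs(X(row, j) - C(crow, j));
  return s;
}

// [[Rcpp::export]]
List cpp_l1_assign(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), d = X.ncol(), K = C.nrow();
  IntegerVector cl(n);
  NumericVector dmin(n);
  double inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = l1_dist(X, i, C, 0, d);
    for (int k = 1; k < K; ++k) {
      double dk = l1_dist(X, i, C, k, d);
      if (dk < bestd) { bestd = dk; best = k; }
    }
    cl[i] = best + 1;
    dmin[i] = bestd;
    inertia += bestd;
  }
  return List::create(_["cluster"] = cl, _["dist"] = dmin,
                      _["inertia"] = inertia);
}

static double column_median(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// [[Rcpp::export]]
List cpp_l1_kmeans(NumericMatrix X, NumericMatrix C0, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), K = C0.nrow();
  NumericMatrix C = clone(C0);
  IntegerVector cl(n, 0);
  NumericVector dmin(n);
  double inertia = R_PosInf;
  int iter = 0, repairs = 0;
  std::vector<double> buf;
  buf.reserve(n);

  for (iter = 0; iter < max_iter; ++iter) {
    // assignment
    bool changed = false;
    inertia = 0.0;
    for (int i = 0; i < n; ++i) {
      int best = 0;
      double bestd = l1_dist(X, i, C, 0, d);
      for (int k = 1; k < K; ++k) {
        double dk = l1_dist(X, i, C, k, d);
        if (dk < bestd) { bestd = dk; best = k; }
      }
      if (cl[i] != best + 1) { changed = true; cl[i] = best + 1; }
      dmin[i] = bestd;
      inertia += bestd;
    }
    if (!changed && iter > 0) break;

    // empty-cluster repair: reseed at the point farthest from its centroid
    std::vector<int> sizes(K, 0);
    for (int i = 0; i < n; ++i) sizes[cl[i] - 1]++;
    for (int k = 0; k < K; ++k) {
      if (sizes[k] == 0) {
        int far = 0;
        double fard = -1.0;
        for (int i = 0; i < n; ++i) {
          if (sizes[cl[i] - 1] > 1 && dmin[i] > fard) { fard = dmin[i]; far = i; }
        }
        sizes[cl[far] - 1]--;
        cl[far] = k + 1;
        sizes[k] = 1;
        dmin[far] = 0.0;
        repairs++;
      }
    }

    // coordinate-wise median update
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < d; ++j) {
        buf.clear();
        for (int i = 0; i < n; ++i)
          if (cl[i] == k + 1) buf.push_back(X(i, j));
        C(k, j) = column_median(buf);
      }
    }
  }

  // final inertia for the returned assignment/centroid pair
  inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = l1_dist(X, i, C, 0, d);
    for (int k = 1; k < K; ++k) {
      double dk = l1_dist(X, i, C, k, d);
      if (dk < bestd) { bestd = dk; best = k; }
    }
    cl[i] = best + 1;
    inertia += bestd;
  }

  return List::create(_["cluster"] = cl, _["centroids"] = C,
                      _["inertia"] = inertia, _["iterations"] = iter,
                      _["repairs"] = repairs);
}
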