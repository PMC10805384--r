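// Kraskov-style conditional mutual information for transfer entropy.
//
// TE_{X->Y}(k, l, u) = I(Y_t ; X_{t-u}^{(l)} | Y_{t-1}^{(k)}) estimated with
// the nearest-neighbour CMI estimator (Frenzel & Pompe form of the
// Kraskov-Stoegbauer-Grassberger algorithm 1): Chebyshev balls in the joint
// space sized by the K-th neighbour, Kozachenko-Leonenko log-probability via
// strict range counts in the marginal subspaces.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// y: n, xp: n x l (source past), yp: n x k (target past).
// centers: 0-based indices over which the Kozachenko-Leonenko average is
// taken (neighbour search always runs over all n points); pass 0..n-1 for
// the full estimator.
// [[Rcpp::export]]
double knn_cmi_cpp(NumericVector y, NumericMatrix xp, NumericMatrix yp,
                   int K, IntegerVector centers) {
  const int n = y.size();
  const int l = xp.ncol();
  const int k = yp.ncol();
  if (n < K + 2) stop("too few points for kNN CMI");

  const double* yv = REAL(y);
  std::vector<const double*> xc(l), yc(k);
  for (int c = 0; c < l; ++c) xc[c] = &xp(0, c);
  for (int c = 0; c < k; ++c) yc[c] = &yp(0, c);

  std::vector<double> dz(n), dy(n), dx(n), tmp(n);
  double acc = 0.0;
  for (int ci = 0; ci < centers.size(); ++ci) {
    const int i = centers[ci];
    // Chebyshev distances per marginal block
    {
      const double* c0 = yc[0];
      const double vi = c0[i];
      for (int j = 0; j < n; ++j) dz[j] = std::fabs(vi - c0[j]);
      for (int c = 1; c < k; ++c) {
        const double* cc = yc[c];
        const double vv = cc[i];
        for (int j = 0; j < n; ++j) {
          double d = std::fabs(vv - cc[j]);
          if (d > dz[j]) dz[j] = d;
        }
      }
    }
    {
      const double* c0 = xc[0];
      const double vi = c0[i];
      for (int j = 0; j < n; ++j) dx[j] = std::fabs(vi - c0[j]);
      for (int c = 1; c < l; ++c) {
        const double* cc = xc[c];
        const double vv = cc[i];
        for (int j = 0; j < n; ++j) {
          double d = std::fabs(vv - cc[j]);
          if (d > dx[j]) dx[j] = d;
        }
      }
    }
    const double yi = yv[i];
    for (int j = 0; j < n; ++j) {
      double dyj = std::fabs(yi - yv[j]);
      dy[j] = dyj;
      double m = dz[j];
      if (dyj > m) m = dyj;
      if (dx[j] > m) m = dx[j];
      tmp[j] = m;
    }
    tmp[i] = R_PosInf;  // exclude self
    std::nth_element(tmp.begin(), tmp.begin() + (K - 1), tmp.end());
    const double eps = tmp[K - 1];

    int nz = 0, nyz = 0, nxz = 0;
    for (int j = 0; j < n; ++j) {
      if (dz[j] < eps) {
        ++nz;
        if (dy[j] < eps) ++nyz;
        if (dx[j] < eps) ++nxz;
      }
    }
    // self always satisfies all strict conditions except distance 0 < eps
    // (eps > 0 after jitter), so remove it from every count
    --nz; --nyz; --nxz;
    acc += R::digamma(nyz + 1.0) + R::digamma(nxz + 1.0) -
           R::digamma(nz + 1.0);
  }
  return R::digamma((double)K) - acc / centers.size();
}

// Zeroth-order local predictor MSE for the Ragwitz embedding criterion:
// predict y from the K nearest neighbours (Chebyshev) in the state space z.
// [[Rcpp::export]]
double knn_predict_mse_cpp(NumericVector y, NumericMatrix z, int K) {
  const int n = y.size();
  const int d = z.ncol();
  std::vector<const double*> zc(d);
  for (int c = 0; c < d; ++c) zc[c] = &z(0, c);
  std::vector<double> dist(n);
  std::vector<int> idx(n);
  double mse = 0.0;
  for (int i = 0; i < n; ++i) {
    {
      const double* c0 = zc[0];
      const double vi = c0[i];
      for (int j = 0; j < n; ++j) dist[j] = std::fabs(vi - c0[j]);
      for (int c = 1; c < d; ++c) {
        const double* cc = zc[c];
        const double vv = cc[i];
        for (int j = 0; j < n; ++j) {
          double dd = std::fabs(vv - cc[j]);
          if (dd > dist[j]) dist[j] = dd;
        }
      }
    }
    dist[i] = R_PosInf;
    for (int j = 0; j < n; ++j) idx[j] = j;
    std::partial_sort(idx.begin(), idx.begin() + K, idx.end(),
                      [&](int a, int b) { return dist[a] < dist[b]; });
    double pred = 0.0;
    for (int m = 0; m < K; ++m) pred += y[idx[m]];
    pred /= K;
    double e = y[i] - pred;
    mse += e * e;
  }
  return mse / n;
}
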