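// Exact t-SNE optimisers (dense O(n^2), 2D output space).
// The staged schedule (phases, perplexities, initialisation) lives in R;
// these routines run the gradient-descent iterations of one phase with
// momentum and adaptive per-coordinate gains.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void apply_update(int n, double momentum, double lr,
                                std::vector<double> &upd,
                                std::vector<double> &gain,
                                const std::vector<double> &grad,
                                double *y) {
  for (int k = 0; k < 2 * n; ++k) {
    const bool match = (grad[k] > 0) == (upd[k] > 0);
    gain[k] = match ? gain[k] * 0.8 : gain[k] + 0.2;
    if (gain[k] < 0.01) gain[k] = 0.01;
    upd[k] = momentum * upd[k] - lr * gain[k] * grad[k];
    y[k] += upd[k];
  }
}

// One optimisation phase for symmetric t-SNE. Y is modified and returned;
// P is the joint affinity matrix (sums to 1).
// [[Rcpp::export]]
NumericMatrix cpp_tsne_phase(NumericMatrix Y_in, NumericMatrix P, int iters,
                             double exaggeration, double momentum,
                             double learning_rate) {
  const int n = Y_in.nrow();
  NumericMatrix Y(clone(Y_in));
  double *y = REAL(Y);                       // column-major: x = y[i], yy = y[n+i]
  const double *p = REAL(P);
  std::vector<double> W((size_t)n * n);
  std::vector<double> upd(2 * n, 0.0), gain(2 * n, 1.0), grad(2 * n);
  for (int it = 0; it < iters; ++it) {
    double Z = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i], yi = y[n + i];
      double *wi = &W[(size_t)i * n];
      for (int j = i + 1; j < n; ++j) {
        const double dx = xi - y[j], dy = yi - y[n + j];
        const double w = 1.0 / (1.0 + dx * dx + dy * dy);
        wi[j] = w;
        W[(size_t)j * n + i] = w;
        Z += 2.0 * w;
      }
      wi[i] = 0.0;
    }
    if (Z < 1e-300) Z = 1e-300;
    const double invZ = 1.0 / Z;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i], yi = y[n + i];
      const double *wi = &W[(size_t)i * n];
      const double *pi = p + (size_t)i * n;   // P symmetric: column i = row i
      double gx = 0.0, gy = 0.0;
      for (int j = 0; j < n; ++j) {
        const double w = wi[j];
        const double mult = (exaggeration * pi[j] - w * invZ) * w;
        gx += mult * (xi - y[j]);
        gy += mult * (yi - y[n + j]);
      }
      grad[i] = 4.0 * gx;
      grad[n + i] = 4.0 * gy;
    }
    apply_update(n, momentum, learning_rate, upd, gain, grad, y);
    // recentre
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) { mx += y[i]; my += y[n + i]; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { y[i] -= mx; y[n + i] -= my; }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}

// One optimisation phase for out-of-sample projection: query points Yq move,
// the reference Yr is frozen. P (q x r) holds affinities of queries towards
// the reference (sums to 1); the repulsive normalisation runs over
// query-reference pairs only.
// [[Rcpp::export]]
NumericMatrix cpp_tsne_phase_fixed(NumericMatrix Yq_in, NumericMatrix Yr,
                                   NumericMatrix P, int iters,
                                   double exaggeration, double momentum,
                                   double learning_rate) {
  const int q = Yq_in.nrow(), r = Yr.nrow();
  NumericMatrix Yq(clone(Yq_in));
  double *y = REAL(Yq);
  const double *yr = REAL(Yr);
  const double *p = REAL(P);
  std::vector<double> W((size_t)q * r);
  std::vector<double> upd(2 * q, 0.0), gain(2 * q, 1.0), grad(2 * q);
  for (int it = 0; it < iters; ++it) {
    double Z = 0.0;
    for (int i = 0; i < q; ++i) {
      const double xi = y[i], yi = y[q + i];
      double *wi = &W[(size_t)i * r];
      for (int j = 0; j < r; ++j) {
        const double dx = xi - yr[j], dy = yi - yr[r + j];
        const double w = 1.0 / (1.0 + dx * dx + dy * dy);
        wi[j] = w;
        Z += w;
      }
    }
    if (Z < 1e-300) Z = 1e-300;
    const double invZ = 1.0 / Z;
    for (int i = 0; i < q; ++i) {
      const double xi = y[i], yi = y[q + i];
      const double *wi = &W[(size_t)i * r];
      double gx = 0.0, gy = 0.0;
      for (int j = 0; j < r; ++j) {
        const double w = wi[j];
        // P is q x r, column-major with q rows
        const double mult = (exaggeration * p[(size_t)j * q + i] - w * invZ) * w;
        gx += mult * (xi - yr[j]);
        gy += mult * (yi - yr[r + j]);
      }
      grad[i] = 4.0 * gx;
      grad[q + i] = 4.0 * gy;
    }
    apply_update(q, momentum, learning_rate, upd, gain, grad, y);
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Yq;
}
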