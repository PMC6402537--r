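// Linear maximum-margin classifier: L2-regularized hinge-loss SVM trained
// by dual coordinate descent (the liblinear algorithm), one-vs-rest over
// k classes.  Cyclic update order (no shuffling) keeps training fully
// deterministic.  The bias is handled by an augmented constant feature
// appended by the caller.  Samples are passed transposed (features x
// samples) so each sample is a contiguous column.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".svm_ovr_train")]]
NumericMatrix svm_ovr_train(const NumericMatrix& Xt, const IntegerVector& y,
                            int n_classes, double C, int max_passes,
                            double tol) {
  const int p = Xt.nrow(), n = Xt.ncol();
  const double* X = REAL(Xt);
  NumericMatrix W(p, n_classes);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = X + (size_t)i * p;
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  std::vector<double> w(p), alpha(n);
  for (int k = 0; k < n_classes; ++k) {
    std::fill(w.begin(), w.end(), 0.0);
    std::fill(alpha.begin(), alpha.end(), 0.0);
    for (int pass = 0; pass < max_passes; ++pass) {
      double max_pg = 0.0;
      for (int i = 0; i < n; ++i) {
        if (qii[i] <= 0.0) continue;
        const double* xi = X + (size_t)i * p;
        const double yi = (y[i] == k + 1) ? 1.0 : -1.0;
        double wx = 0.0;
        for (int j = 0; j < p; ++j) wx += w[j] * xi[j];
        const double g = yi * wx - 1.0;
        double pg = g;
        if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
        else if (alpha[i] >= C) pg = std::max(g, 0.0);
        if (std::fabs(pg) > 1e-12) {
          const double old = alpha[i];
          double a = old - g / qii[i];
          a = std::min(std::max(a, 0.0), C);
          alpha[i] = a;
          const double d = (a - old) * yi;
          if (d != 0.0)
            for (int j = 0; j < p; ++j) w[j] += d * xi[j];
        }
        if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      }
      if (max_pg < tol) break;
    }
    for (int j = 0; j < p; ++j) W(j, k) = w[j];
  }
  return W;
}
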