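#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized L1-loss linear SVM, solved in the dual by coordinate
// descent (the LIBLINEAR algorithm). The bias is handled by augmenting an
// implicit constant feature of value 1. The sweep order over examples is
// fixed, so the solution is deterministic for a given input ordering.
//
// X: n x p matrix of training patterns (rows = examples)
// y: labels in {-1, +1}
// Returns w (length p) and b.
// [[Rcpp::export]]
List linsvm_fit(NumericMatrix X, NumericVector y, double C = 1.0,
                double tol = 1e-8, int max_epochs = 2000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p + 1, 0.0); // last entry = bias weight
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented constant feature
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[p]; // bias term times constant feature
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        w[p] += d;
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector wv(p);
  for (int j = 0; j < p; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[p]);
}
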