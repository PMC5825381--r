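#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear soft-margin C-SVM trained by dual coordinate descent
// (L1 hinge loss; Hsieh et al. 2008). The bias is handled by an augmented
// constant feature of value 1, the usual linear-solver convention.
// X is n x d (row-major here via flat vector), y in {-1,+1}.
static std::vector<double> svm_train_dense(const std::vector<double>& X,
                                           const std::vector<double>& y,
                                           int n, int d, double C,
                                           double tol, int max_epochs) {
  std::vector<double> w(d + 1, 0.0);     // last entry is the bias weight
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0;                      // augmented bias feature
    for (int j = 0; j < d; ++j) q += X[i * d + j] * X[i * d + j];
    Qii[i] = q;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned int state = 88172645u + (unsigned)n * 2654435761u;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // xorshift shuffle for deterministic but decorrelated sweeps
    for (int i = n - 1; i > 0; --i) {
      state ^= state << 13; state ^= state >> 17; state ^= state << 5;
      int j = state % (i + 1);
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      double g = -1.0;
      const double* xi = &X[i * d];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        double old = alpha[i];
        double a = old - g / Qii[i];
        if (a < 0.0) a = 0.0;
        if (a > C) a = C;
        alpha[i] = a;
        double delta = (a - old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
        w[d] += delta;
      }
    }
    if (max_pg < tol) break;
  }
  return w;
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
NumericVector svm_train_cpp(NumericMatrix X, NumericVector y, double C,
                            double tol = 1e-4, int max_epochs = 400) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr((size_t)n * d), yv(n);
  for (int i = 0; i < n; ++i) {
    yv[i] = y[i];
    for (int j = 0; j < d; ++j) Xr[(size_t)i * d + j] = X(i, j);
  }
  std::vector<double> w = svm_train_dense(Xr, yv, n, d, C, tol, max_epochs);
  NumericVector out(d + 1);
  for (int j = 0; j <= d; ++j) out[j] = w[j];
  return out;   // w[1..d], then bias
}

// z-score columns of train/test using train statistics (in place);
// zero-variance columns are left centred only
static void standardize(std::vector<double>& Xtr, std::vector<double>& Xte,
                        int ntr, int nte, int d) {
  for (int j = 0; j < d; ++j) {
    double mu = 0.0;
    for (int i = 0; i < ntr; ++i) mu += Xtr[(size_t)i * d + j];
    mu /= ntr;
    double ss = 0.0;
    for (int i = 0; i < ntr; ++i) {
      double v = Xtr[(size_t)i * d + j] - mu;
      ss += v * v;
    }
    double sd = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
    if (sd <= 0.0) sd = 1.0;
    for (int i = 0; i < ntr; ++i)
      Xtr[(size_t)i * d + j] = (Xtr[(size_t)i * d + j] - mu) / sd;
    for (int i = 0; i < nte; ++i)
      Xte[(size_t)i * d + j] = (Xte[(size_t)i * d + j] - mu) / sd;
  }
}

// Hamming decoding of binary dichotomy outputs against a K x L codebook;
// ties broken by lowest class index
static int hamming_decode_row(const std::vector<int>& bits,
                              const IntegerMatrix& code) {
  int K = code.nrow(), L = code.ncol();
  int best = 0, bestd = L + 1;
  for (int k = 0; k < K; ++k) {
    int dist = 0;
    for (int l = 0; l < L; ++l) if (bits[l] != code(k, l)) ++dist;
    if (dist < bestd) { bestd = dist; best = k; }
  }
  return best;
}

// Train ECOC (one SVM per dichotomy, z-scored features) on (Xtr, ytr) and
// predict classes for Xte. ytr is 0-based class index; codebook K x L with
// entries 0/1. Returns 0-based predictions.
// [[Rcpp::export(name = ".ecoc_fit_predict_cpp")]]
IntegerVector ecoc_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                   NumericMatrix Xte, IntegerMatrix codebook,
                                   double C, double tol = 1e-4,
                                   int max_epochs = 400) {
  int ntr = Xtr.nrow(), nte = Xte.nrow(), d = Xtr.ncol();
  int L = codebook.ncol();
  std::vector<double> A((size_t)ntr * d), B((size_t)nte * d);
  for (int i = 0; i < ntr; ++i)
    for (int j = 0; j < d; ++j) A[(size_t)i * d + j] = Xtr(i, j);
  for (int i = 0; i < nte; ++i)
    for (int j = 0; j < d; ++j) B[(size_t)i * d + j] = Xte(i, j);
  standardize(A, B, ntr, nte, d);

  std::vector<std::vector<int> > outputs(nte, std::vector<int>(L));
  std::vector<double> yb(ntr);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < ntr; ++i)
      yb[i] = codebook(ytr[i], l) == 1 ? 1.0 : -1.0;
    std::vector<double> w = svm_train_dense(A, yb, ntr, d, C, tol, max_epochs);
    for (int i = 0; i < nte; ++i) {
      double s = w[d];
      for (int j = 0; j < d; ++j) s += w[j] * B[(size_t)i * d + j];
      outputs[i][l] = s > 0 ? 1 : 0;
    }
  }
  IntegerVector pred(nte);
  for (int i = 0; i < nte; ++i)
    pred[i] = hamming_decode_row(outputs[i], codebook);
  return pred;
}

// CV ECOC accuracy on a column subset, allocation-light inner path shared
// by the single-subset and the all-spheres entry points. cols are 0-based
// column indices into the n x D matrix X (column-major, as R stores it).
static double ecoc_cv_subset(const double* X, int n, int D,
                             const std::vector<int>& cols,
                             const int* y, const int* fold, int nf,
                             const IntegerMatrix& codebook,
                             double C, double tol, int max_epochs,
                             std::vector<double>& Atr,
                             std::vector<double>& Ate,
                             std::vector<double>& yb,
                             std::vector<int>& bits) {
  int d = (int)cols.size();
  int L = codebook.ncol();
  int correct = 0, total = 0;
  for (int f = 1; f <= nf; ++f) {
    int ntr = 0, nte = 0;
    for (int i = 0; i < n; ++i) (fold[i] == f ? nte : ntr)++;
    if (nte == 0 || ntr == 0) continue;
    Atr.resize((size_t)ntr * d); Ate.resize((size_t)nte * d);
    std::vector<int> ytr(ntr), yte(nte);
    int a = 0, b = 0;
    for (int i = 0; i < n; ++i) {
      if (fold[i] == f) { yte[b] = y[i]; ++b; } else { ytr[a] = y[i]; ++a; }
    }
    for (int j = 0; j < d; ++j) {
      const double* col = X + (size_t)cols[j] * n;
      int ia = 0, ib = 0;
      for (int i = 0; i < n; ++i) {
        if (fold[i] == f) Ate[(size_t)(ib++) * d + j] = col[i];
        else Atr[(size_t)(ia++) * d + j] = col[i];
      }
    }
    standardize(Atr, Ate, ntr, nte, d);
    bits.assign((size_t)nte * L, 0);
    yb.resize(ntr);
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < ntr; ++i)
        yb[i] = codebook(ytr[i], l) == 1 ? 1.0 : -1.0;
      std::vector<double> w = svm_train_dense(Atr, yb, ntr, d, C, tol,
                                              max_epochs);
      for (int i = 0; i < nte; ++i) {
        double s = w[d];
        for (int j = 0; j < d; ++j) s += w[j] * Ate[(size_t)i * d + j];
        bits[(size_t)i * L + l] = s > 0 ? 1 : 0;
      }
    }
    for (int i = 0; i < nte; ++i) {
      std::vector<int> bi(bits.begin() + (size_t)i * L,
                          bits.begin() + (size_t)(i + 1) * L);
      if (hamming_decode_row(bi, codebook) == yte[i]) ++correct;
    }
    total += nte;
  }
  return total > 0 ? (double)correct / total : NA_REAL;
}

// Cross-validated ECOC accuracy over given folds on a feature subset.
// X n x d (already restricted to the candidate voxels), y 0-based classes,
// fold 1-based fold ids. Used to score searchlight spheres cheaply.
// [[Rcpp::export(name = ".ecoc_cv_accuracy_cpp")]]
double ecoc_cv_accuracy_cpp(NumericMatrix X, IntegerVector y,
                            IntegerVector fold, IntegerMatrix codebook,
                            double C, double tol = 1e-4,
                            int max_epochs = 400) {
  int n = X.nrow(), d = X.ncol();
  int nf = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > nf) nf = fold[i];
  std::vector<int> cols(d);
  for (int j = 0; j < d; ++j) cols[j] = j;
  std::vector<double> Atr, Ate, yb;
  std::vector<int> bits;
  return ecoc_cv_subset(X.begin(), n, d, cols, y.begin(),
                        fold.begin(), nf, codebook, C, tol,
                        max_epochs, Atr, Ate, yb, bits);
}

// Score every sphere by inner-CV ECOC accuracy. X is the full train-split
// pattern matrix (n x n_roi_voxels); spheres is a list of integer vectors of
// 1-based column indices. Returns one accuracy per sphere.
// [[Rcpp::export(name = ".score_spheres_cpp")]]
NumericVector score_spheres_cpp(NumericMatrix X, IntegerVector y,
                                IntegerVector fold, List spheres,
                                IntegerMatrix codebook, double C,
                                double tol = 1e-4, int max_epochs = 400) {
  int n = X.nrow(), D = X.ncol();
  int ns = spheres.size();
  int nf = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > nf) nf = fold[i];
  NumericVector out(ns);
  std::vector<double> Atr, Ate, yb;
  std::vector<int> bits;
  const double* Xp = X.begin();
  const int* yp = y.begin();
  const int* fp = fold.begin();
  for (int s = 0; s < ns; ++s) {
    IntegerVector colsR = spheres[s];
    std::vector<int> cols(colsR.size());
    for (int j = 0; j < (int)cols.size(); ++j) cols[j] = colsR[j] - 1;
    out[s] = ecoc_cv_subset(Xp, n, D, cols, yp, fp, nf, codebook, C, tol,
                            max_epochs, Atr, Ate, yb, bits);
  }
  return out;
}
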