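#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Elastic-net objective, glmnet parameterization on standardized predictors:
//   (1/2n) * sum_i (y_i - b0 - x_i'b)^2 + lambda * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)
// Predictors are standardized with 1/n variances; y is centered but not scaled.
// Coefficients are mapped back to the original scale before returning.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent on a Gram formulation: G = (1/n) Xs'Xs, r = (1/n) Xs'yc.
// Columns with G[j][j] == 0 (constant predictors) keep coefficient 0.
static void cd_solve(const std::vector< std::vector<double> >& G,
                     const std::vector<double>& r,
                     double lambda, double alpha,
                     std::vector<double>& b,
                     int max_iter = 1000, double tol = 1e-12) {
  const int p = (int) r.size();
  if (lambda == 0.0 && p == 1) {
    b[0] = (G[0][0] > 0.0) ? r[0] / G[0][0] : 0.0;
    return;
  }
  if (lambda == 0.0 && p == 2) {
    double det = G[0][0] * G[1][1] - G[0][1] * G[1][0];
    if (G[1][1] <= 0.0) { b[1] = 0.0; b[0] = (G[0][0] > 0.0) ? r[0] / G[0][0] : 0.0; return; }
    if (G[0][0] <= 0.0) { b[0] = 0.0; b[1] = r[1] / G[1][1]; return; }
    if (std::fabs(det) > 1e-12) {
      b[0] = (r[0] * G[1][1] - r[1] * G[0][1]) / det;
      b[1] = (r[1] * G[0][0] - r[0] * G[1][0]) / det;
      return;
    }
    // collinear: put all weight on the first predictor
    b[0] = r[0] / G[0][0]; b[1] = 0.0;
    return;
  }
  const double lam1 = lambda * alpha, lam2 = lambda * (1.0 - alpha);
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (G[j][j] <= 0.0) { b[j] = 0.0; continue; }
      double rho = r[j];
      for (int k = 0; k < p; ++k) if (k != j) rho -= G[j][k] * b[k];
      double bnew = soft_threshold(rho, lam1) / (G[j][j] + lam2);
      delta = std::max(delta, std::fabs(bnew - b[j]));
      b[j] = bnew;
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export(name = ".enet_cd_cpp")]]
List enet_cd_cpp(NumericMatrix X, NumericVector y, double lambda, double alpha) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xm(p), xs(p);
  double ym = mean(y);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { double d = X(i, j) - m; v += d * d; }
    xm[j] = m;
    xs[j] = std::sqrt(v / n);
  }
  std::vector< std::vector<double> > G(p, std::vector<double>(p, 0.0));
  std::vector<double> r(p, 0.0), b(p, 0.0);
  bool any_const = false;
  for (int j = 0; j < p; ++j) {
    if (xs[j] == 0.0) { any_const = true; continue; }
    for (int k = j; k < p; ++k) {
      if (xs[k] == 0.0) continue;
      double s = 0.0;
      for (int i = 0; i < n; ++i)
        s += (X(i, j) - xm[j]) / xs[j] * (X(i, k) - xm[k]) / xs[k];
      G[j][k] = G[k][j] = s / n;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (X(i, j) - xm[j]) / xs[j] * (y[i] - ym);
    r[j] = s / n;
  }
  cd_solve(G, r, lambda, alpha, b);
  NumericVector beta(p);
  double icpt = ym;
  for (int j = 0; j < p; ++j) {
    beta[j] = (xs[j] > 0.0) ? b[j] / xs[j] : 0.0;
    icpt -= beta[j] * xm[j];
  }
  return List::create(_["beta"] = beta, _["intercept"] = icpt,
                      _["constant_columns"] = any_const);
}

static inline double pearson_r(const std::vector<double>& a, const std::vector<double>& bv) {
  const int n = (int) a.size();
  double ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += bv[i]; }
  ma /= n; mb /= n;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = bv[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

static inline double nmae_stat(const std::vector<double>& truth, const std::vector<double>& pred) {
  const int n = (int) truth.size();
  double mt = 0.0;
  for (int i = 0; i < n; ++i) mt += truth[i];
  mt /= n;
  double mae = 0.0, denom = 0.0;
  for (int i = 0; i < n; ++i) {
    mae += std::fabs(truth[i] - pred[i]);
    denom += std::fabs(truth[i] - mt);
  }
  if (denom <= 0.0) return NA_REAL;
  return mae / denom;
}

// Replicated 80/20 cross-validation of the six candidate models.
//   y        response (length n)
//   xb       blood predictor (length n)
//   clin     n x 5 clinical matrix (alcohol, tobacco, hpv, age, sex)
//   test_idx R x n_test matrix of 1-based test indices per replicate
//   lambda_grid  candidate penalties (used when fixed_penalty is false;
//                chosen per fit by leave-one-out error within the training split)
//   alpha    elastic-net mixing
//   fixed_penalty / penalty  bypass the grid with one penalty value
// Returns, per model (1..6), replicate vectors of test r, test NMAE, the
// blood coefficient a1, clinical coefficient a2 (NA for model 1), intercept
// b0 and the penalty used, all on the original predictor scale.
// [[Rcpp::export(name = ".cv_engine_cpp")]]
List cv_engine_cpp(NumericVector y, NumericVector xb, NumericMatrix clin,
                   IntegerMatrix test_idx, NumericVector lambda_grid,
                   double alpha, bool fixed_penalty, double penalty) {
  const int n = y.size(), R = test_idx.nrow(), ntest = test_idx.ncol();
  const int n_models = 6;
  List out(n_models);
  std::vector<NumericMatrix> store;
  for (int m = 0; m < n_models; ++m) {
    NumericMatrix M(R, 6); // r, nmae, a1, a2, b0, lambda
    std::fill(M.begin(), M.end(), NA_REAL);
    store.push_back(M);
  }
  std::vector<int> is_test(n);
  std::vector<int> tr_idx; tr_idx.reserve(n);

  for (int rep = 0; rep < R; ++rep) {
    std::fill(is_test.begin(), is_test.end(), 0);
    for (int k = 0; k < ntest; ++k) is_test[test_idx(rep, k) - 1] = 1;
    tr_idx.clear();
    for (int i = 0; i < n; ++i) if (!is_test[i]) tr_idx.push_back(i);
    const int ntr = (int) tr_idx.size();

    for (int m = 0; m < n_models; ++m) {
      const int p = (m == 0) ? 1 : 2;
      // assemble training predictors
      std::vector< std::vector<double> > X(p, std::vector<double>(ntr));
      std::vector<double> ytr(ntr);
      for (int t = 0; t < ntr; ++t) {
        X[0][t] = xb[tr_idx[t]];
        if (p == 2) X[1][t] = clin(tr_idx[t], m - 1);
        ytr[t] = y[tr_idx[t]];
      }
      // standardize (1/n variance) on the training split
      std::vector<double> xm(p), xs(p);
      for (int j = 0; j < p; ++j) {
        double mu = 0.0;
        for (int t = 0; t < ntr; ++t) mu += X[j][t];
        mu /= ntr;
        double v = 0.0;
        for (int t = 0; t < ntr; ++t) { double d = X[j][t] - mu; v += d * d; }
        xm[j] = mu; xs[j] = std::sqrt(v / ntr);
      }
      double ym = 0.0;
      for (int t = 0; t < ntr; ++t) ym += ytr[t];
      ym /= ntr;
      // standardized columns and centered response
      std::vector< std::vector<double> > Xs(p, std::vector<double>(ntr, 0.0));
      std::vector<double> yc(ntr);
      for (int t = 0; t < ntr; ++t) yc[t] = ytr[t] - ym;
      for (int j = 0; j < p; ++j)
        if (xs[j] > 0.0)
          for (int t = 0; t < ntr; ++t) Xs[j][t] = (X[j][t] - xm[j]) / xs[j];
      // raw sums for downdating
      std::vector< std::vector<double> > Sxx(p, std::vector<double>(p, 0.0));
      std::vector<double> Sxy(p, 0.0), S1x(p, 0.0);
      double S1y = 0.0;
      for (int t = 0; t < ntr; ++t) {
        for (int j = 0; j < p; ++j) {
          S1x[j] += Xs[j][t];
          Sxy[j] += Xs[j][t] * yc[t];
          for (int k = j; k < p; ++k) Sxx[j][k] += Xs[j][t] * Xs[k][t];
        }
        S1y += yc[t];
      }
      for (int j = 0; j < p; ++j)
        for (int k = 0; k < j; ++k) Sxx[j][k] = Sxx[k][j];

      double lam_use = penalty;
      if (!fixed_penalty) {
        // leave-one-out MSE over the penalty grid
        double best_err = R_PosInf;
        double best_lam = lambda_grid[0];
        std::vector< std::vector<double> > Gl(p, std::vector<double>(p));
        std::vector<double> rl(p), bl(p, 0.0);
        for (int g = 0; g < lambda_grid.size(); ++g) {
          const double lam = lambda_grid[g];
          double err = 0.0;
          for (int h = 0; h < ntr; ++h) {
            const double nm1 = (double) (ntr - 1);
            for (int j = 0; j < p; ++j) {
              rl[j] = (Sxy[j] - Xs[j][h] * yc[h]) / nm1;
              for (int k = j; k < p; ++k) {
                Gl[j][k] = (Sxx[j][k] - Xs[j][h] * Xs[k][h]) / nm1;
                Gl[k][j] = Gl[j][k];
              }
            }
            std::fill(bl.begin(), bl.end(), 0.0);
            cd_solve(Gl, rl, lam, alpha, bl, 200, 1e-10);
            double b0l = (S1y - yc[h]) / nm1;
            for (int j = 0; j < p; ++j)
              b0l -= bl[j] * (S1x[j] - Xs[j][h]) / nm1; // fold LOO means into intercept
            double pred = b0l;
            for (int j = 0; j < p; ++j) pred += bl[j] * Xs[j][h];
            double e = yc[h] - pred;
            err += e * e;
          }
          if (err < best_err - 1e-15 ||
              (std::fabs(err - best_err) <= 1e-15 && lam > best_lam)) {
            best_err = err; best_lam = lam;
          }
        }
        lam_use = best_lam;
      }

      // final fit on the full training split
      std::vector< std::vector<double> > G(p, std::vector<double>(p));
      std::vector<double> rr(p), b(p, 0.0);
      for (int j = 0; j < p; ++j) {
        rr[j] = Sxy[j] / ntr;
        for (int k = 0; k < p; ++k) G[j][k] = Sxx[j][k] / ntr;
      }
      cd_solve(G, rr, lam_use, alpha, b);
      std::vector<double> beta(p);
      double icpt = ym;
      for (int j = 0; j < p; ++j) {
        beta[j] = (xs[j] > 0.0) ? b[j] / xs[j] : 0.0;
        icpt -= beta[j] * xm[j];
      }
      // evaluate on the test split
      std::vector<double> truth(ntest), pred(ntest);
      for (int k = 0; k < ntest; ++k) {
        int i = test_idx(rep, k) - 1;
        truth[k] = y[i];
        double yhat = icpt + beta[0] * xb[i];
        if (p == 2) yhat += beta[1] * clin(i, m - 1);
        pred[k] = yhat;
      }
      NumericMatrix& M = store[m];
      M(rep, 0) = pearson_r(truth, pred);
      M(rep, 1) = nmae_stat(truth, pred);
      M(rep, 2) = beta[0];
      M(rep, 3) = (p == 2) ? beta[1] : NA_REAL;
      M(rep, 4) = icpt;
      M(rep, 5) = lam_use;
    }
  }
  for (int m = 0; m < n_models; ++m) {
    NumericMatrix& M = store[m];
    out[m] = List::create(_["r"] = M(_, 0), _["nmae"] = M(_, 1),
                          _["a1"] = M(_, 2), _["a2"] = M(_, 3),
                          _["intercept"] = M(_, 4), _["lambda"] = M(_, 5));
  }
  return out;
}
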