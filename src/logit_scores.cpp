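// Batch logistic deviance fitting for per-gene association scores.
// IRLS with step-halving, hand-rolled for small predictor counts so a
// whole genome (tens of thousands of fits) runs in well under a second.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int MAXP = 9;  // intercept + up to 8 predictors

struct LogitFit {
  double beta[MAXP];
  int p;
  double deviance;
  bool converged;
  bool separation;
};

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Solve A b = rhs (p x p, row-major, symmetric positive definite-ish) by
// Gaussian elimination with partial pivoting. Returns false if singular.
static bool solve_small(double* A, double* rhs, double* b, int p) {
  double M[MAXP][MAXP + 1];
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) M[i][j] = A[i * p + j];
    M[i][p] = rhs[i];
  }
  for (int c = 0; c < p; ++c) {
    int piv = c;
    double best = std::fabs(M[c][c]);
    for (int r = c + 1; r < p; ++r) {
      double v = std::fabs(M[r][c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != c) for (int j = c; j <= p; ++j) std::swap(M[c][j], M[piv][j]);
    double d = M[c][c];
    for (int j = c; j <= p; ++j) M[c][j] /= d;
    for (int r = 0; r < p; ++r) {
      if (r == c) continue;
      double f = M[r][c];
      if (f != 0.0) for (int j = c; j <= p; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int i = 0; i < p; ++i) b[i] = M[i][p];
  return true;
}

// D: n x p design (column-major, includes intercept column of ones).
// y in {0,1}. Writes the fit into `out`.
static void irls_logit(const double* D, int n, int p, const double* y,
                       int maxit, double tol, double sep_tol,
                       LogitFit& out) {
  double beta[MAXP] = {0.0};
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  beta[0] = std::log(ybar / (1.0 - ybar));

  std::vector<double> eta(n), mu(n);
  double dev = 0.0;
  for (int i = 0; i < n; ++i) {
    eta[i] = beta[0];
    mu[i] = ybar;
    dev += y[i] * eta[i] - softplus(eta[i]);
  }
  dev *= -2.0;

  bool converged = false;
  double A[MAXP * MAXP], rhs[MAXP], bnew[MAXP], step[MAXP], cand[MAXP];

  for (int it = 0; it < maxit; ++it) {
    for (int j = 0; j < p * p; ++j) A[j] = 0.0;
    for (int j = 0; j < p; ++j) rhs[j] = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = mu[i];
      double w = m * (1.0 - m);
      if (w < 1e-10) w = 1e-10;
      double z = eta[i] + (y[i] - m) / w;
      for (int j = 0; j < p; ++j) {
        double dj = D[j * n + i];
        double wdj = w * dj;
        rhs[j] += wdj * z;
        for (int k = 0; k <= j; ++k) A[j * p + k] += wdj * D[k * n + i];
      }
    }
    for (int j = 0; j < p; ++j)
      for (int k = j + 1; k < p; ++k) A[j * p + k] = A[k * p + j];

    if (!solve_small(A, rhs, bnew, p)) break;

    for (int j = 0; j < p; ++j) step[j] = bnew[j] - beta[j];
    double dev_new = dev;
    for (int h = 0; h < 30; ++h) {
      for (int j = 0; j < p; ++j) cand[j] = beta[j] + step[j];
      double d2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int j = 0; j < p; ++j) e += D[j * n + i] * cand[j];
        d2 += y[i] * e - softplus(e);
      }
      d2 *= -2.0;
      if (std::isfinite(d2) && d2 <= dev + 1e-8) {
        for (int j = 0; j < p; ++j) beta[j] = cand[j];
        dev_new = d2;
        break;
      }
      for (int j = 0; j < p; ++j) step[j] *= 0.5;
    }
    // refresh eta/mu at the accepted beta
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < p; ++j) e += D[j * n + i] * beta[j];
      eta[i] = e;
      mu[i] = 1.0 / (1.0 + std::exp(-e));
    }
    if (std::fabs(dev - dev_new) / (std::fabs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      converged = true;
      break;
    }
    dev = dev_new;
  }

  bool sep = true;
  for (int i = 0; i < n; ++i) {
    bool pinned = (y[i] > 0.5) ? (mu[i] > 1.0 - sep_tol) : (mu[i] < sep_tol);
    if (!pinned) { sep = false; break; }
  }

  for (int j = 0; j < p; ++j) out.beta[j] = beta[j];
  out.p = p;
  out.deviance = dev;
  out.converged = converged;
  out.separation = sep;
}

// Standardize a column in place; returns false for constant columns.
static bool standardize(double* x, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { x[i] -= m; ss += x[i] * x[i]; }
  if (ss <= 0.0) return false;
  double s = std::sqrt(ss / (n - 1));
  for (int i = 0; i < n; ++i) x[i] /= s;
  return true;
}

static double null_deviance(const vec& y) {
  double n1 = accu(y), n = y.n_elem;
  double pbar = n1 / n;
  return -2.0 * (n1 * std::log(pbar) + (n - n1) * std::log(1.0 - pbar));
}

// [[Rcpp::export]]
Rcpp::List cpp_logit_deviance(const arma::mat& X, const arma::vec& y,
                              int maxit, double tol, double sep_tol) {
  const int n = y.n_elem;
  if ((int)X.n_cols > MAXP - 1)
    Rcpp::stop("at most %d predictors are supported", MAXP - 1);
  double null_dev = null_deviance(y);

  // build standardized design, dropping constant columns
  std::vector<double> D((X.n_cols + 1) * n);
  for (int i = 0; i < n; ++i) D[i] = 1.0;
  std::vector<int> kept;
  int p = 1;
  for (uword j = 0; j < X.n_cols; ++j) {
    std::copy(X.colptr(j), X.colptr(j) + n, D.begin() + p * n);
    if (standardize(&D[p * n], n)) {
      kept.push_back(j + 1);
      ++p;
    }
  }

  LogitFit fit;
  if (p == 1) {
    double pbar = mean(y);
    fit.beta[0] = std::log(pbar / (1.0 - pbar));
    fit.p = 1;
    fit.deviance = null_dev;
    fit.converged = true;
    fit.separation = false;
  } else {
    irls_logit(D.data(), n, p, y.memptr(), maxit, tol, sep_tol, fit);
  }
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = std::vector<double>(fit.beta,
                                                      fit.beta + fit.p),
    Rcpp::Named("kept_columns") = kept,
    Rcpp::Named("null_deviance") = null_dev,
    Rcpp::Named("residual_deviance") = fit.deviance,
    Rcpp::Named("converged") = fit.converged,
    Rcpp::Named("separation") = fit.separation);
}

// Score every gene on every platform plus integratively.
// platforms: list of N x G matrices (column g = gene g across samples,
// i.e. transposed so per-gene reads are contiguous).
// avail: G x D 0/1 matrix (precomputed availability).
// [[Rcpp::export]]
Rcpp::List cpp_score_genes(const Rcpp::List& platforms,
                           const arma::imat& avail,
                           const arma::vec& y,
                           int maxit, double tol, double sep_tol) {
  const int D = platforms.size();
  const int G = avail.n_rows;
  const int n = y.n_elem;
  if (D > MAXP - 1) Rcpp::stop("too many platforms");

  std::vector<const double*> Xd(D);
  for (int d = 0; d < D; ++d) {
    Rcpp::NumericMatrix M = platforms[d];
    if (M.nrow() != n || M.ncol() != G)
      Rcpp::stop("platform matrices must be samples x genes");
    Xd[d] = REAL(M);
  }

  double null_dev = null_deviance(y);
  const double* yp = y.memptr();

  Rcpp::NumericMatrix single(G, D);
  Rcpp::NumericVector integ(G);
  Rcpp::IntegerMatrix s_flag(G, D), s_conv(G, D);
  Rcpp::IntegerVector i_flag(G), i_conv(G);
  std::fill(single.begin(), single.end(), NA_REAL);
  std::fill(s_conv.begin(), s_conv.end(), 1);
  std::fill(i_conv.begin(), i_conv.end(), 1);

  std::vector<double> Dmat((D + 1) * n);
  for (int i = 0; i < n; ++i) Dmat[i] = 1.0;
  std::vector<double> Done(2 * n);
  for (int i = 0; i < n; ++i) Done[i] = 1.0;

  LogitFit fit;
  for (int g = 0; g < G; ++g) {
    int p = 1, navail = 0;
    for (int d = 0; d < D; ++d) {
      if (!avail(g, d)) continue;
      ++navail;
      // gene column -> standardized predictor column
      double* col = &Dmat[p * n];
      std::copy(Xd[d] + (size_t)g * n, Xd[d] + (size_t)(g + 1) * n, col);
      bool ok = standardize(col, n);
      if (!ok) { single(g, d) = 0.0; continue; }

      // single-platform fit
      std::copy(col, col + n, Done.begin() + n);
      irls_logit(Done.data(), n, 2, yp, maxit, tol, sep_tol, fit);
      double sc = null_dev - fit.deviance;
      if (fit.separation) { sc = null_dev; s_flag(g, d) = 1; }
      single(g, d) = sc > 0.0 ? sc : 0.0;
      s_conv(g, d) = fit.converged ? 1 : 0;
      ++p;
    }
    if (navail == 0) { integ[g] = NA_REAL; continue; }
    if (p == 1) { integ[g] = 0.0; continue; }
    irls_logit(Dmat.data(), n, p, yp, maxit, tol, sep_tol, fit);
    double sc = null_dev - fit.deviance;
    if (fit.separation) { sc = null_dev; i_flag[g] = 1; }
    integ[g] = sc > 0.0 ? sc : 0.0;
    i_conv[g] = fit.converged ? 1 : 0;
  }

  return Rcpp::List::create(
    Rcpp::Named("single") = single,
    Rcpp::Named("integrative") = integ,
    Rcpp::Named("null_deviance") = null_dev,
    Rcpp::Named("single_separation") = s_flag,
    Rcpp::Named("single_converged") = s_conv,
    Rcpp::Named("integrative_separation") = i_flag,
    Rcpp::Named("integrative_converged") = i_conv);
}
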