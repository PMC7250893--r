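// Numerical cores for state-space reconstruction methods.
// Kept deliberately simple: full pairwise distances (series are short),
// stable (distance, index) tie-breaking so results are reproducible and
// comparable against brute-force reference implementations.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<double> pairwise_dist(const NumericMatrix& X) {
  const int n = X.nrow(), E = X.ncol();
  std::vector<double> D(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < E; ++c) {
        const double d = X(i, c) - X(j, c);
        s += d * d;
      }
      const double d = std::sqrt(s);
      D[static_cast<size_t>(i) * n + j] = d;
      D[static_cast<size_t>(j) * n + i] = d;
    }
  }
  return D;
}

static double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  const size_t n = x.size();
  if (n < 2) return NA_REAL;
  double mx = 0.0, my = 0.0;
  for (size_t i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Leave-one-out simplex projection: for every state row, predict its
// next-step target from the k nearest other rows, exponential weighting by
// distance to the nearest neighbour (floored at 1e-12 for duplicate states).
// [[Rcpp::export]]
NumericVector cpp_simplex_loo(NumericMatrix states, NumericVector target, int k) {
  const int n = states.nrow();
  if (target.size() != n) stop("states/target length mismatch");
  std::vector<double> D = pairwise_dist(states);
  NumericVector pred(n);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    for (int j = 0; j < n; ++j)
      if (j != i) cand.push_back(std::make_pair(D[static_cast<size_t>(i) * n + j], j));
    const int kk = std::min<int>(k, static_cast<int>(cand.size()));
    if (kk < 1) stop("no neighbours available");
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    const double d1 = std::max(cand[0].first, 1e-12);
    double sw = 0.0, sp = 0.0;
    for (int m = 0; m < kk; ++m) {
      const double w = std::exp(-cand[m].first / d1);
      sw += w;
      sp += w * target[cand[m].second];
    }
    pred[i] = sp / sw;
  }
  return pred;
}

// Cross-map skill for a set of library subsamples.  `D` is the full
// distance matrix of the library variable's embedding rows, `cause` the
// contemporaneous (already lag-aligned) cause values at those rows, `libs`
// a list of 1-based row-index vectors (one library subsample each).
// Predictions are made at every row; the row itself is never its own
// neighbour.  Returns one Pearson rho per library.
// [[Rcpp::export]]
NumericVector cpp_cross_map_rho(NumericMatrix D, NumericVector cause, List libs, int k) {
  const int n = D.nrow();
  if (cause.size() != n) stop("D/cause size mismatch");
  const int nlib = libs.size();
  NumericVector out(nlib);
  std::vector<double> bestd(k);
  std::vector<int> bestj(k);
  std::vector<double> pred(n), obs(n);
  for (int li = 0; li < nlib; ++li) {
    IntegerVector lib0 = libs[li];
    std::vector<int> lib(lib0.begin(), lib0.end());
    std::sort(lib.begin(), lib.end());  // ascending index => stable ties
    const int L = static_cast<int>(lib.size());
    for (int i = 0; i < n; ++i) {
      int m = 0;  // current number of stored neighbours
      for (int q = 0; q < L; ++q) {
        const int j = lib[q] - 1;
        if (j == i) continue;
        const double d = D[static_cast<size_t>(i) * n + j];
        if (m < k) {
          int pos = m;
          while (pos > 0 && bestd[pos - 1] > d) --pos;
          for (int t = m; t > pos; --t) { bestd[t] = bestd[t - 1]; bestj[t] = bestj[t - 1]; }
          bestd[pos] = d; bestj[pos] = j; ++m;
        } else if (d < bestd[k - 1]) {
          int pos = k - 1;
          while (pos > 0 && bestd[pos - 1] > d) --pos;
          for (int t = k - 1; t > pos; --t) { bestd[t] = bestd[t - 1]; bestj[t] = bestj[t - 1]; }
          bestd[pos] = d; bestj[pos] = j;
        }
      }
      if (m < 1) stop("empty library for a prediction point");
      const double d1 = std::max(bestd[0], 1e-12);
      double sw = 0.0, sp = 0.0;
      for (int t = 0; t < m; ++t) {
        const double w = std::exp(-bestd[t] / d1);
        sw += w;
        sp += w * cause[bestj[t]];
      }
      pred[i] = sp / sw;
      obs[i] = cause[i];
    }
    out[li] = pearson(pred, obs);
  }
  return out;
}

// Sequential locally weighted maps.  For each target row, weight all other
// library rows by exp(-theta * d / dbar) with dbar the mean distance to the
// library, and solve the weighted linear model (intercept + E coordinates)
// by SVD with relative singular-value truncation.  Returns the per-row
// coefficient matrix, predictions, and dbar values.
// [[Rcpp::export]]
List cpp_smap(arma::mat X, arma::vec y, double theta, bool exclude_target,
              double svd_tol) {
  const arma::uword m = X.n_rows, E = X.n_cols;
  arma::mat coef(m, E + 1, arma::fill::zeros);
  arma::vec pred(m), dbar_out(m);
  arma::mat D(m, m, arma::fill::zeros);
  for (arma::uword i = 0; i < m; ++i)
    for (arma::uword j = i + 1; j < m; ++j) {
      const double d = arma::norm(X.row(i) - X.row(j), 2);
      D(i, j) = d;
      D(j, i) = d;
    }
  for (arma::uword t = 0; t < m; ++t) {
    arma::uvec lib;
    if (exclude_target) {
      lib.set_size(m - 1);
      arma::uword p = 0;
      for (arma::uword j = 0; j < m; ++j) if (j != t) lib(p++) = j;
    } else {
      lib = arma::regspace<arma::uvec>(0, m - 1);
    }
    arma::vec d(lib.n_elem);
    for (arma::uword q = 0; q < lib.n_elem; ++q) d(q) = D(t, lib(q));
    const double dbar = arma::mean(d);
    if (!(dbar > 0.0))
      stop("degenerate geometry: all embedding states are identical");
    arma::vec w = arma::exp(-theta * d / dbar);
    arma::mat A(lib.n_elem, E + 1);
    A.col(0) = w;
    for (arma::uword j = 0; j < E; ++j) A.col(j + 1) = w % X.submat(lib, arma::uvec{j});
    arma::vec B = w % y(lib);
    arma::mat U, V;
    arma::vec s;
    if (!arma::svd_econ(U, s, V, A)) stop("SVD failed in S-map solve");
    const double smax = s.max();
    arma::vec c(E + 1, arma::fill::zeros);
    arma::vec ub = U.t() * B;
    for (arma::uword r = 0; r < s.n_elem; ++r)
      if (s(r) > svd_tol * smax) c += V.col(r) * (ub(r) / s(r));
    coef.row(t) = c.t();
    pred(t) = c(0) + arma::dot(X.row(t).t(), c.subvec(1, E));
    dbar_out(t) = dbar;
  }
  return List::create(Named("coefficients") = coef,
                      Named("predictions") = pred,
                      Named("dbar") = dbar_out);
}
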