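// Compiled evaluation kernels for the two reference adapters. Each call
// scores one block of repetitions: the caller draws all subsample indices
// (and optional shuffle permutations) from its R-side RNG stream, so results
// are identical in distribution and determinism semantics to the pure-R
// adapter path; only the per-repetition arithmetic moves to C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Merge two individually sorted vectors into one sorted vector (O(n)); used
// to maintain running order statistics across repetition blocks.
// [[Rcpp::export(name = ".merge_sorted")]]
NumericVector merge_sorted(const NumericVector& a, const NumericVector& b) {
  NumericVector out(a.size() + b.size());
  std::merge(a.begin(), a.end(), b.begin(), b.end(), out.begin());
  return out;
}

// Gather subsample rows into train/test matrices column-wise (the matrices
// are column-major, so row-wise copies would stride).
static void gather(const arma::mat& x, const arma::vec& y,
                   const IntegerMatrix& idx, const int r, const int n_tr,
                   arma::mat& xtr, arma::mat& xte,
                   arma::vec& ytr, arma::vec& yte) {
  const int p = x.n_cols;
  const int n_te = xte.n_rows;
  for (int c = 0; c < p; ++c) {
    const double* col = x.colptr(c);
    double* tr = xtr.colptr(c);
    double* te = xte.colptr(c);
    for (int i = 0; i < n_tr; ++i) tr[i] = col[idx(r, i) - 1];
    for (int i = 0; i < n_te; ++i) te[i] = col[idx(r, n_tr + i) - 1];
  }
  for (int i = 0; i < n_tr; ++i) ytr(i) = y(idx(r, i) - 1);
  for (int i = 0; i < n_te; ++i) yte(i) = y(idx(r, n_tr + i) - 1);
}

static double r2_score(const arma::vec& obs, const arma::vec& pred) {
  const double mu = arma::mean(obs);
  const double sst = arma::accu(arma::square(obs - mu));
  if (sst == 0.0) return NA_REAL;
  return 1.0 - arma::accu(arma::square(obs - pred)) / sst;
}

// Standardize train/test with the train split's mean and population sd
// (zero-variance columns are centred only), matching the R-path scaler.
static void standardize(arma::mat& xtr, arma::mat& xte) {
  const arma::rowvec mu = arma::mean(xtr, 0);
  arma::rowvec sd = arma::sqrt(
      arma::mean(arma::square(xtr), 0) - arma::square(mu));
  sd.elem(arma::find(sd == 0.0)).ones();
  xtr.each_row() -= mu;
  xtr.each_row() /= sd;
  xte.each_row() -= mu;
  xte.each_row() /= sd;
}

// [[Rcpp::export(name = ".ols_block_eval")]]
List ols_block_eval(const arma::mat& x, const arma::vec& y,
                    const IntegerMatrix& idx, const int n_tr,
                    const Nullable<IntegerMatrix> perm = R_NilValue) {
  const int k = idx.nrow();
  const int d_n = idx.ncol();
  const int n_te = d_n - n_tr;
  const int p = x.n_cols;
  const bool shuffled = perm.isNotNull();
  IntegerMatrix pm;
  if (shuffled) pm = perm.get();

  NumericVector acc_tr(k), acc_te(k);
  arma::mat xtr(n_tr, p), xte(n_te, p);
  arma::vec ytr(n_tr), yte(n_te);

  for (int r = 0; r < k; ++r) {
    gather(x, y, idx, r, n_tr, xtr, xte, ytr, yte);
    if (shuffled) {
      arma::vec ys(n_tr);
      for (int i = 0; i < n_tr; ++i) ys(i) = ytr(pm(r, i) - 1);
      ytr = ys;
    }
    standardize(xtr, xte);
    arma::mat atr = arma::join_rows(arma::ones(n_tr), xtr);
    arma::vec coef;
    if (!arma::solve(coef, atr, ytr, arma::solve_opts::no_approx)) {
      // rank deficient: minimum-norm least squares, as in the R adapter
      coef = arma::pinv(atr) * ytr;
    }
    const arma::mat ate = arma::join_rows(arma::ones(n_te), xte);
    acc_tr[r] = r2_score(ytr, atr * coef);
    acc_te[r] = r2_score(yte, ate * coef);
  }
  return List::create(Named("tr") = acc_tr, Named("te") = acc_te);
}

// Mean target of the k_nb nearest training rows (self included when scoring
// the training split, as in standard KNN regression implementations).
// `d2` and `buf` are caller-provided workspaces reused across repetitions.
static void knn_predict(const arma::mat& xq, const arma::mat& xtr,
                        const arma::vec& ytr, const int k_nb,
                        arma::mat& d2, std::vector<std::pair<double, int> >& buf,
                        arma::vec& out) {
  const int nq = xq.n_rows;
  const int ntr = xtr.n_rows;
  // squared distances (up to a per-query constant) via the Gram trick, laid
  // out (train x query) so each query's distance vector is contiguous
  d2 = -2.0 * xtr * xq.t();
  d2.each_col() += arma::sum(arma::square(xtr), 1);

  // bounded max-heap scan: keep the lexicographically smallest k_nb
  // (distance, index) pairs per query
  for (int i = 0; i < nq; ++i) {
    const double* di = d2.colptr(i);
    buf.clear();
    for (int j = 0; j < k_nb; ++j) buf.push_back(std::make_pair(di[j], j));
    std::make_heap(buf.begin(), buf.end());
    for (int j = k_nb; j < ntr; ++j) {
      const std::pair<double, int> cand(di[j], j);
      if (cand < buf.front()) {
        std::pop_heap(buf.begin(), buf.end());
        buf.back() = cand;
        std::push_heap(buf.begin(), buf.end());
      }
    }
    double s = 0.0;
    for (int j = 0; j < k_nb; ++j) s += ytr(buf[j].second);
    out(i) = s / k_nb;
  }
}

// [[Rcpp::export(name = ".knn_block_eval")]]
List knn_block_eval(const arma::mat& x, const arma::vec& y,
                    const IntegerMatrix& idx, const int n_tr,
                    const int n_neighbors,
                    const Nullable<IntegerMatrix> perm = R_NilValue) {
  const int k = idx.nrow();
  const int d_n = idx.ncol();
  const int n_te = d_n - n_tr;
  const int p = x.n_cols;
  const int k_nb = std::min(n_neighbors, n_tr);
  const bool shuffled = perm.isNotNull();
  IntegerMatrix pm;
  if (shuffled) pm = perm.get();

  NumericVector acc_tr(k), acc_te(k);
  arma::mat xtr(n_tr, p), xte(n_te, p);
  arma::vec ytr(n_tr), yte(n_te);
  arma::mat d2tr(n_tr, n_tr), d2te(n_tr, n_te);
  arma::vec ptr(n_tr), pte(n_te);
  std::vector<std::pair<double, int> > buf(n_tr);

  for (int r = 0; r < k; ++r) {
    gather(x, y, idx, r, n_tr, xtr, xte, ytr, yte);
    if (shuffled) {
      arma::vec ys(n_tr);
      for (int i = 0; i < n_tr; ++i) ys(i) = ytr(pm(r, i) - 1);
      ytr = ys;
    }
    standardize(xtr, xte);
    knn_predict(xtr, xtr, ytr, k_nb, d2tr, buf, ptr);
    knn_predict(xte, xtr, ytr, k_nb, d2te, buf, pte);
    acc_tr[r] = r2_score(ytr, ptr);
    acc_te[r] = r2_score(yte, pte);
  }
  return List::create(Named("tr") = acc_tr, Named("te") = acc_te);
}
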