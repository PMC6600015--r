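// Hot path of the nested-CV component selection for single-response PLS:
// for one training fold, loop over inner folds, standardize on inner-training
// lines, fit PLS1 by NIPALS (which for a single response needs no inner
// iteration: w is proportional to X'y) and accumulate squared test errors for
// every component count 1..pcMax. Returns the RMS curve indexed by component
// count. Semantics identical to the R reference path; only the loop lives in
// C++ because permutation backgrounds rerun it tens of thousands of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(".cppPls1InnerRms")]]
arma::vec cppPls1InnerRms(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& folds, const int pcMax) {
  const int n = X.n_rows;
  arma::vec sse(pcMax, arma::fill::zeros);
  const int kmax = folds.max();
  for (int k = 1; k <= kmax; ++k) {
    arma::uvec te = arma::find(folds == k);
    arma::uvec tr = arma::find(folds != k);
    if (te.n_elem == 0 || tr.n_elem < 2) continue;
    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    arma::rowvec ctr = arma::mean(Xtr, 0);
    arma::rowvec scl = arma::stddev(Xtr, 0, 0);  // sample SD (N - 1)
    arma::uvec ok = arma::find(scl > 0);
    arma::mat Xd = Xtr.cols(ok);
    Xd.each_row() -= ctr.cols(ok);
    Xd.each_row() /= scl.cols(ok);
    arma::mat Xt = X.submat(te, ok);
    Xt.each_row() -= ctr.cols(ok);
    Xt.each_row() /= scl.cols(ok);
    const double ym = arma::mean(ytr);
    arma::vec yd = ytr - ym;
    arma::vec yte = y.elem(te);
    arma::vec pred(te.n_elem);
    pred.fill(ym);
    const int A = std::min(pcMax,
                           std::min((int)Xd.n_cols, (int)Xd.n_rows - 1));
    int a = 0;
    for (; a < A; ++a) {
      arma::vec w = Xd.t() * yd;
      const double nw = arma::norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      arma::vec t = Xd * w;
      const double tt = arma::dot(t, t);
      if (tt < 1e-28) break;
      arma::vec pl = (Xd.t() * t) / tt;
      const double q = arma::dot(yd, t) / tt;
      Xd -= t * pl.t();
      yd -= q * t;
      arma::vec tte = Xt * w;
      Xt -= tte * pl.t();
      pred += q * tte;
      sse[a] += arma::dot(pred - yte, pred - yte);
    }
    const double tail = arma::dot(pred - yte, pred - yte);
    for (int b = a; b < pcMax; ++b) sse[b] += tail;
  }
  return arma::sqrt(sse / n);
}
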