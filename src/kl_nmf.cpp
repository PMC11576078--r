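// Multiplicative-update NMF under the generalized Kullback-Leibler
// divergence. The alternating W/H updates are the classic ones that
// monotonically decrease
//   KL(A; WH) = sum_ij [ A_ij log(A_ij / (WH)_ij) - A_ij + (WH)_ij ].
// Initial factors are drawn in R (so the R RNG contract holds); this file
// only iterates them. The loop keeps all work buffers preallocated,
// fuses the division floor into a single pass, and evaluates the loss
// only at checkpoints, where the A-only part sum_{A>0} A log A - sum A
// is hoisted out as a constant.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FLOOR = 1e-12;  // guards 0/0 inside divisions

// [[Rcpp::export(name = ".kl_nmf_fit_cpp")]]
Rcpp::List kl_nmf_fit_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                          int max_iter, double tol, int check_every) {
  const uword p = A.n_rows, n = A.n_cols;
  mat WH(p, n), R(p, n), Hnum(H.n_rows, n), Wnum(p, W.n_cols);

  // constant part of the loss: sum_{A>0} A log A - sum A
  double const_a = 0.0;
  for (uword i = 0; i < A.n_elem; ++i)
    if (A[i] > 0) const_a += A[i] * std::log(A[i]);
  const_a -= accu(A);
  // KL(A;WH) = const_a - sum_{A>0} A log(WH) + sum(WH), WH floored on read
  auto gkld = [&](const mat& WHx) {
    double s_log = 0.0, s_wh = 0.0;
    const double* wh = WHx.memptr();
    const double* a = A.memptr();
    for (uword i = 0; i < WHx.n_elem; ++i) {
      double v = wh[i] < FLOOR ? FLOOR : wh[i];
      s_wh += v;
      if (a[i] > 0) s_log += a[i] * std::log(v);
    }
    return const_a - s_log + s_wh;
  };
  // R = A / max(WH, FLOOR) in one fused pass
  auto ratio = [&](const mat& WHx) {
    const double* wh = WHx.memptr();
    const double* a = A.memptr();
    double* r = R.memptr();
    for (uword i = 0; i < WHx.n_elem; ++i) {
      double v = wh[i] < FLOOR ? FLOOR : wh[i];
      r[i] = a[i] / v;
    }
  };

  WH = W * H;
  std::vector<double> history;
  history.push_back(gkld(WH));
  double kl_prev = history.back();
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // H update: H_aj *= [W^T (A/WH)]_aj / sum_i W_ia
    ratio(WH);
    Hnum = W.t() * R;
    vec wsum = sum(W, 0).t() + FLOOR;
    H %= Hnum;
    H.each_col() /= wsum;
    WH = W * H;

    // W update: W_ia *= [(A/WH) H^T]_ia / sum_j H_aj
    ratio(WH);
    Wnum = R * H.t();
    rowvec hsum = sum(H, 1).t() + FLOOR;
    W %= Wnum;
    W.each_row() /= hsum;
    WH = W * H;

    if (it % check_every == 0 || it == max_iter) {
      double kl = gkld(WH);
      history.push_back(kl);
      double denom = std::max(std::abs(kl_prev), 1e-300);
      if (std::abs(kl_prev - kl) / denom < tol) { converged = true; break; }
      kl_prev = kl;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("kl_history") = history,
      Rcpp::Named("iterations") = std::min(it, max_iter),
      Rcpp::Named("converged") = converged);
}
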