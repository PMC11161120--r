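// Weighted multinomial-logistic likelihood kernels.
//
// The adaptive fitter compresses the forgetting-factor weighted data into a
// table of distinct covariate rows X (n x p) with non-negative outcome
// weights Wt (n x (M+1)); column 0 of Wt is the no-event reference category,
// columns 1..M the reliable marks. The weighted log-likelihood is
//   l = sum_x [ sum_m Wt(x,m) * log p_m(x) + Wt(x,0) * log p_0(x) ]
// with p_m(x) = exp(u_m)/(1 + sum exp(u)), u_m = mu_m + x' theta_m.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOGP_FLOOR = std::log(1e-12);

// Row-wise stable log(1 + sum_m exp(u_m)) and probabilities.
static void softmax_row(const arma::rowvec& u, arma::rowvec& p, double& lse) {
  double m = 0.0;  // reference category has linear predictor 0
  double umax = u.max();
  if (umax > m) m = umax;
  double s = std::exp(-m);
  for (arma::uword j = 0; j < u.n_elem; ++j) s += std::exp(u[j] - m);
  lse = m + std::log(s);
  for (arma::uword j = 0; j < u.n_elem; ++j) p[j] = std::exp(u[j] - lse);
}

// [[Rcpp::export]]
List cpp_mnl_eval(const arma::mat& X, const arma::mat& Wt,
                  const arma::vec& mu, const arma::mat& Theta,
                  bool want_grad) {
  const arma::uword n = X.n_rows, M = mu.n_elem;
  arma::mat U = X * Theta;           // n x M
  U.each_row() += mu.t();
  double ll = 0.0;
  arma::vec gmu(M, arma::fill::zeros);
  arma::mat gtheta(X.n_cols, M, arma::fill::zeros);
  arma::mat resid;                    // n x M, filled only if want_grad
  if (want_grad) resid.set_size(n, M);
  arma::rowvec p(M);
  double lse;
  for (arma::uword i = 0; i < n; ++i) {
    softmax_row(U.row(i), p, lse);
    double w0 = Wt(i, 0), wtot = w0;
    double lp0 = -lse < LOGP_FLOOR ? LOGP_FLOOR : -lse;
    ll += w0 * lp0;
    for (arma::uword m = 0; m < M; ++m) {
      double w = Wt(i, m + 1);
      wtot += w;
      if (w > 0.0) {
        double lp = U(i, m) - lse;
        if (lp < LOGP_FLOOR) lp = LOGP_FLOOR;
        ll += w * lp;
      }
    }
    if (want_grad)
      for (arma::uword m = 0; m < M; ++m)
        resid(i, m) = Wt(i, m + 1) - wtot * p[m];
  }
  if (want_grad) {
    gmu = arma::sum(resid, 0).t();
    gtheta = X.t() * resid;
  }
  return List::create(_["loglik"] = ll, _["gmu"] = gmu, _["gtheta"] = gtheta);
}

// Hessian of the weighted log-likelihood restricted to a coordinate set.
// coord_mark: 1-based mark index per coordinate; coord_cov: 0 for the
// intercept (base rate), else 1-based covariate column of X.
// Assembled blockwise with BLAS products: the (mu, mu) block is a weighted
// crossproduct of the probability matrix; blocks involving theta coordinates
// use covariate-masked probability columns.
// [[Rcpp::export]]
arma::mat cpp_mnl_hess(const arma::mat& X, const arma::mat& Wt,
                       const arma::vec& mu, const arma::mat& Theta,
                       const arma::ivec& coord_mark,
                       const arma::ivec& coord_cov) {
  const arma::uword n = X.n_rows, M = mu.n_elem, d = coord_mark.n_elem;
  arma::mat U = X * Theta;
  U.each_row() += mu.t();
  arma::mat P(n, M);
  arma::vec wtot(n);
  {
    arma::rowvec p(M);
    double lse;
    for (arma::uword i = 0; i < n; ++i) {
      softmax_row(U.row(i), p, lse);
      P.row(i) = p;
      wtot[i] = arma::accu(Wt.row(i));
    }
  }
  // partition the coordinate set
  std::vector<arma::uword> imu, ith;
  for (arma::uword j = 0; j < d; ++j)
    (coord_cov[j] == 0 ? imu : ith).push_back(j);
  const arma::uword nmu = imu.size(), nth = ith.size();
  arma::mat H(d, d, arma::fill::zeros);
  arma::mat Pw = P.each_col() % wtot;        // n x M
  if (nmu > 0) {
    arma::uvec mmu(nmu);
    for (arma::uword a = 0; a < nmu; ++a) mmu[a] = coord_mark[imu[a]] - 1;
    arma::mat Ps = P.cols(mmu), Pws = Pw.cols(mmu);
    arma::mat B = Ps.t() * Pws;              // sum w p_i p_j
    arma::rowvec dg = arma::sum(Pws, 0);     // sum w p_i
    for (arma::uword a = 0; a < nmu; ++a)
      for (arma::uword b = 0; b < nmu; ++b)
        H(imu[a], imu[b]) = B(a, b) - (a == b ? dg[a] : 0.0);
  }
  if (nth > 0) {
    // Q: weighted covariate-masked probability of each theta coordinate
    arma::mat Q(n, nth), U2(n, nth);
    for (arma::uword a = 0; a < nth; ++a) {
      const arma::uword m = coord_mark[ith[a]] - 1,
                        cv = coord_cov[ith[a]] - 1;
      U2.col(a) = X.col(cv) % P.col(m);
      Q.col(a) = wtot % U2.col(a);
    }
    if (nmu > 0) {
      arma::uvec mmu(nmu);
      for (arma::uword a = 0; a < nmu; ++a) mmu[a] = coord_mark[imu[a]] - 1;
      arma::mat Bm = P.cols(mmu).t() * Q;    // nmu x nth: sum w x p_mu p_th
      arma::rowvec qs = arma::sum(Q, 0);
      for (arma::uword a = 0; a < nmu; ++a)
        for (arma::uword b = 0; b < nth; ++b) {
          double v = Bm(a, b);
          if (coord_mark[imu[a]] == coord_mark[ith[b]]) v -= qs[b];
          H(imu[a], ith[b]) = v;
          H(ith[b], imu[a]) = v;
        }
    }
    arma::mat Bt = Q.t() * U2;               // nth x nth: sum w x x' p p'
    for (arma::uword a = 0; a < nth; ++a)
      for (arma::uword b = a; b < nth; ++b) {
        double v = Bt(a, b);
        if (coord_mark[ith[a]] == coord_mark[ith[b]]) {
          const arma::uword cvb = coord_cov[ith[b]] - 1;
          v -= arma::dot(Q.col(a), X.col(cvb));  // sum w x_a x_b p_m
        }
        H(ith[a], ith[b]) = v;
        H(ith[b], ith[a]) = v;
      }
  }
  return H;
}

// Per-bin categorical probabilities for prediction and the independence
// composition: returns n x (M+1) with column 0 the no-event probability.
// [[Rcpp::export]]
arma::mat cpp_mnl_probs(const arma::mat& X, const arma::vec& mu,
                        const arma::mat& Theta) {
  const arma::uword n = X.n_rows, M = mu.n_elem;
  arma::mat U = X * Theta;
  U.each_row() += mu.t();
  arma::mat P(n, M + 1);
  arma::rowvec p(M);
  double lse;
  for (arma::uword i = 0; i < n; ++i) {
    softmax_row(U.row(i), p, lse);
    P(i, 0) = std::exp(-lse);
    for (arma::uword m = 0; m < M; ++m) P(i, m + 1) = p[m];
  }
  return P;
}
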