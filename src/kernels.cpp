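// Fast inner loops for the wrapper selectors: pooled-covariance linear
// discriminant (MLHD) prediction, leave-one-out cross-validation, and
// greedy Wilks-Lambda forward selection. The R-level mlhd_fit() /
// wilks_lambda() are the readable reference implementations; tests assert
// exact agreement between the two routes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pooled within-class covariance with a ridge guard: if inversion fails,
// eps * mean(diag) is added to the diagonal (and escalated once).
static arma::mat pooled_cov_inv(const arma::mat& X, const arma::ivec& y,
                                int G, double ridge_eps) {
  const int n = X.n_rows, k = X.n_cols;
  arma::mat W(k, k, arma::fill::zeros);
  for (int g = 1; g <= G; ++g) {
    arma::uvec idx = arma::find(y == g);
    arma::mat Xg = X.rows(idx);
    arma::rowvec mu = arma::mean(Xg, 0);
    Xg.each_row() -= mu;
    W += Xg.t() * Xg;
  }
  W /= std::max(1, n - G);
  double md = arma::mean(W.diag());
  if (md <= 0.0) md = 1.0;
  arma::mat Winv;
  if (arma::inv_sympd(Winv, W)) return Winv;
  arma::mat Wr = W + ridge_eps * md * arma::eye(k, k);
  if (arma::inv_sympd(Winv, Wr)) return Winv;
  Wr = W + 1e-4 * md * arma::eye(k, k);
  if (!arma::inv_sympd(Winv, Wr))
    stop("pooled covariance singular even after ridge guard");
  return Winv;
}

static arma::ivec mlhd_predict_core(const arma::mat& Xtrain,
                                    const arma::ivec& ytrain,
                                    const arma::mat& Xtest,
                                    int G, double ridge_eps) {
  const int k = Xtrain.n_cols;
  arma::mat Winv = pooled_cov_inv(Xtrain, ytrain, G, ridge_eps);
  arma::mat Mu(G, k);           // class means
  for (int g = 1; g <= G; ++g) {
    arma::uvec idx = arma::find(ytrain == g);
    Mu.row(g - 1) = arma::mean(Xtrain.rows(idx), 0);
  }
  // linear discriminant scores: x' Winv mu_g - 0.5 mu_g' Winv mu_g
  arma::mat A = Mu * Winv;                  // G x k
  arma::vec c(G);
  for (int g = 0; g < G; ++g) c(g) = 0.5 * arma::dot(A.row(g), Mu.row(g));
  arma::mat S = Xtest * A.t();              // ntest x G
  S.each_row() -= c.t();
  arma::ivec pred(Xtest.n_rows);
  for (arma::uword i = 0; i < Xtest.n_rows; ++i) {
    arma::uword best = S.row(i).index_max();
    pred(i) = (int)best + 1;
  }
  return pred;
}

static IntegerVector ivec_to_R(const arma::ivec& v) {
  IntegerVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = (int)v(i);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mlhd_predict(const arma::mat& Xtrain,
                               const arma::ivec& ytrain,
                               const arma::mat& Xtest,
                               int n_classes, double ridge_eps) {
  return ivec_to_R(mlhd_predict_core(Xtrain, ytrain, Xtest, n_classes,
                                     ridge_eps));
}

// [[Rcpp::export]]
List cpp_loocv(const arma::mat& X, const arma::ivec& y, int n_classes,
               double ridge_eps) {
  const int n = X.n_rows;
  arma::ivec pred(n);
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    arma::uvec tr = arma::find(all != (arma::uword)i);
    arma::mat Xtr = X.rows(tr);
    arma::ivec ytr = y.elem(tr);
    arma::mat Xte = X.row(i);
    arma::ivec p = mlhd_predict_core(Xtr, ytr, Xte, n_classes, ridge_eps);
    pred(i) = p(0);
  }
  int ok = 0;
  for (int i = 0; i < n; ++i) if (pred(i) == y(i)) ++ok;
  return List::create(_["accuracy"] = (double)ok / n,
                      _["predictions"] = ivec_to_R(pred));
}

// accuracy-only LOOCV fast path for the selector inner loops
// [[Rcpp::export]]
double cpp_loocv_acc(const arma::mat& X, const arma::ivec& y, int n_classes,
                     double ridge_eps) {
  const int n = X.n_rows;
  int ok = 0;
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    arma::uvec tr = arma::find(all != (arma::uword)i);
    arma::ivec p = mlhd_predict_core(X.rows(tr), y.elem(tr), X.row(i),
                                     n_classes, ridge_eps);
    if (p(0) == y(i)) ++ok;
  }
  return (double)ok / n;
}

// [[Rcpp::export]]
double cpp_resub_accuracy(const arma::mat& X, const arma::ivec& y,
                          int n_classes, double ridge_eps) {
  arma::ivec pred = mlhd_predict_core(X, y, X, n_classes, ridge_eps);
  int ok = 0;
  for (arma::uword i = 0; i < X.n_rows; ++i) if (pred(i) == y(i)) ++ok;
  return (double)ok / X.n_rows;
}

// log det of a scatter matrix, with a tiny ridge if needed
static double logdet_safe(const arma::mat& M) {
  double val, sign;
  if (arma::log_det_sympd(val, M)) return val;
  double md = arma::mean(M.diag());
  if (md <= 0.0) md = 1.0;
  arma::mat Mr = M + 1e-10 * md * arma::eye(M.n_rows, M.n_cols);
  arma::log_det(val, sign, Mr);
  return val;
}

// Wilks Lambda = det(W)/det(T) on the given columns
static double wilks_cols(const arma::mat& X, const arma::ivec& y, int G,
                         const arma::uvec& cols) {
  arma::mat Xs = X.cols(cols);
  const int n = Xs.n_rows, k = Xs.n_cols;
  arma::rowvec gm = arma::mean(Xs, 0);
  arma::mat Xc = Xs;
  Xc.each_row() -= gm;
  arma::mat T = Xc.t() * Xc;
  arma::mat W(k, k, arma::fill::zeros);
  for (int g = 1; g <= G; ++g) {
    arma::uvec idx = arma::find(y == g);
    arma::mat Xg = Xs.rows(idx);
    arma::rowvec mu = arma::mean(Xg, 0);
    Xg.each_row() -= mu;
    W += Xg.t() * Xg;
  }
  (void)n;
  return std::exp(logdet_safe(W) - logdet_safe(T));
}

// [[Rcpp::export]]
double cpp_wilks_lambda(const arma::mat& X, const arma::ivec& y,
                        int n_classes) {
  arma::uvec cols = arma::regspace<arma::uvec>(0, X.n_cols - 1);
  return wilks_cols(X, y, n_classes, cols);
}

// Greedy forward selection on the partial-Lambda F test. Adds at each step
// the candidate with the smallest partial-Lambda p-value while p < alpha,
// up to max_steps variables (and while residual df allow).
// [[Rcpp::export]]
List cpp_greedy_forward(const arma::mat& X, const arma::ivec& y,
                        int n_classes, double alpha, int max_steps) {
  const int n = X.n_rows, p = X.n_cols, G = n_classes;
  std::vector<int> sel;                 // 0-based selected columns
  std::vector<double> lambdas, pvals, fstats;
  std::vector<bool> used(p, false);
  double lambda_cur = 1.0;
  int q = 0;
  while (q < max_steps && (n - G - q) >= 1) {
    double best_p = 2.0, best_F = -1.0, best_lambda = 1.0;
    int best_j = -1;
    const double df1 = G - 1.0, df2 = n - G - q;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      arma::uvec cols(q + 1);
      for (int t = 0; t < q; ++t) cols(t) = sel[t];
      cols(q) = j;
      double lam = wilks_cols(X, y, G, cols);
      double pl = lam / lambda_cur;     // partial Lambda
      if (pl > 1.0) pl = 1.0;
      if (pl < 1e-300) pl = 1e-300;
      double F = (df2 / df1) * (1.0 - pl) / pl;
      double pv = R::pf(F, df1, df2, 0, 0);
      if (pv < best_p || (pv == best_p && F > best_F)) {
        best_p = pv; best_F = F; best_j = j; best_lambda = lam;
      }
    }
    if (best_j < 0 || best_p >= alpha) break;
    sel.push_back(best_j);
    used[best_j] = true;
    lambdas.push_back(best_lambda);
    pvals.push_back(best_p);
    fstats.push_back(best_F);
    lambda_cur = best_lambda;
    ++q;
  }
  IntegerVector selR(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) selR[i] = sel[i] + 1;
  return List::create(_["selected"] = selR,
                      _["lambda"] = wrap(lambdas),
                      _["F"] = wrap(fstats),
                      _["p_value"] = wrap(pvals));
}
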