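// Newton solver for L2-penalized logistic regression with a warm-started
// path over the inverse-penalty grid C.  Objective (sklearn convention):
//   f(b0, w) = sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ] + ||w||^2 / (2C)
// with eta = b0 + X w; the intercept is never penalized.  The nested-CV
// loop fits this objective ~1e5 times per audit, hence compiled code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double ridge_obj(const vec& eta, const vec& y, const vec& w, double C) {
  double nll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    // log(1+exp(e)) = max(e,0) + log1p(exp(-|e|)), overflow-safe
    nll += (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e))) - y(i) * e;
  }
  return nll + 0.5 / C * dot(w, w);
}

static vec sigmoid(const vec& eta) {
  vec p(eta.n_elem);
  for (uword i = 0; i < eta.n_elem; ++i)
    p(i) = 1.0 / (1.0 + std::exp(-eta(i)));
  return p;
}

// One damped-Newton fit at fixed C starting from beta (length p+1,
// intercept first).  Writes the objective trace into `trace` if non-null.
static void newton_fit(const mat& Xa, const vec& y, double C, vec& beta,
                       double tol, int maxit, std::vector<double>* trace) {
  const uword p = Xa.n_cols - 1;
  vec eta = Xa * beta;
  double obj = ridge_obj(eta, y, beta.subvec(1, p), C);
  if (trace) trace->push_back(obj);
  for (int it = 0; it < maxit; ++it) {
    vec pr = sigmoid(eta);
    vec g = Xa.t() * (pr - y);
    g.subvec(1, p) += beta.subvec(1, p) / C;
    vec wts = clamp(pr % (1.0 - pr), 1e-10, 0.25);
    mat H = Xa.t() * (Xa.each_col() % wts);
    for (uword j = 1; j <= p; ++j) H(j, j) += 1.0 / C;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-8;
      step = solve(H, g);
    }
    // backtracking line search guaranteeing monotone descent
    double t = 1.0, gs = dot(g, step);
    vec cand;
    double obj_new = obj;
    bool moved = false;
    for (int h = 0; h < 40; ++h) {
      cand = beta - t * step;
      vec eta_c = Xa * cand;
      double o = ridge_obj(eta_c, y, cand.subvec(1, p), C);
      if (o <= obj - 1e-4 * t * gs || o < obj) {
        beta = cand; eta = eta_c; obj_new = o; moved = true; break;
      }
      t *= 0.5;
    }
    if (trace) trace->push_back(obj_new);
    if (!moved) break;                       // numerically converged
    double drop = obj - obj_new;
    obj = obj_new;
    if (drop < tol * (1.0 + std::fabs(obj))) break;
  }
}

// [[Rcpp::export(name = ".ridge_logistic_path")]]
arma::mat ridge_logistic_path(const arma::mat& X, const arma::vec& y,
                              const arma::vec& C_grid,
                              double tol = 1e-8, int maxit = 60) {
  const uword p = X.n_cols;
  mat Xa = join_horiz(ones<vec>(X.n_rows), X);
  mat out(p + 1, C_grid.n_elem, fill::zeros);
  // warm-start along ascending C (heavy shrinkage first, where w ~ 0)
  uvec ord = sort_index(C_grid);
  vec beta(p + 1, fill::zeros);
  for (uword k = 0; k < ord.n_elem; ++k) {
    newton_fit(Xa, y, C_grid(ord(k)), beta, tol, maxit, nullptr);
    out.col(ord(k)) = beta;
  }
  return out;
}

// [[Rcpp::export(name = ".ridge_logistic_trace")]]
Rcpp::List ridge_logistic_trace(const arma::mat& X, const arma::vec& y,
                                double C, double tol = 1e-8, int maxit = 60) {
  const uword p = X.n_cols;
  mat Xa = join_horiz(ones<vec>(X.n_rows), X);
  vec beta(p + 1, fill::zeros);
  std::vector<double> tr;
  newton_fit(Xa, y, C, beta, tol, maxit, &tr);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("objective") = tr);
}
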