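// Gradient-descent core of neighborhood regularized logistic matrix
// factorization.  Mirrors the reference R implementation exactly: the
// objective is recorded at the current point before each update and the
// stop rule compares successive recorded values.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// one pass over the logits: accumulates sum(W % softplus(Z)) with the
// overflow-safe softplus and fills P = logistic(Z) from the same exp()
static inline double softplus_sum_and_logistic(const mat& Z, const mat& W,
                                               mat& P) {
  double acc = 0.0;
  for (uword i = 0; i < Z.n_elem; ++i) {
    double z = Z(i);
    double e = std::exp(-std::fabs(z));        // exp(-|z|), never overflows
    acc += W(i) * ((z > 0.0 ? z : 0.0) + std::log1p(e));
    P(i) = (z >= 0.0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
  }
  return acc;
}

// [[Rcpp::export(name = ".nrlmf_fit_cpp")]]
Rcpp::List nrlmf_fit_cpp(const arma::mat& Y,
                         const arma::mat& Ld, const arma::mat& Lt,
                         arma::mat U, arma::mat V,
                         double c, double lambda_d, double lambda_t,
                         double alpha_reg, double beta_reg,
                         double lr, int max_iter, double tol,
                         bool adagrad) {
  const mat W = 1.0 + c * Y - Y;
  const mat LdA = lambda_d * eye(Y.n_rows, Y.n_rows) + alpha_reg * Ld;
  const mat LtA = lambda_t * eye(Y.n_cols, Y.n_cols) + beta_reg * Lt;

  mat gU(size(U), fill::zeros), gV(size(V), fill::zeros);
  const double eps = 1e-8;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double obj_prev = datum::inf;
  bool converged = false;

  mat P(Y.n_rows, Y.n_cols);
  for (int it = 0; it < max_iter; ++it) {
    mat Z = U * V.t();
    mat RU = LdA * U;
    mat RV = LtA * V;
    double obj = softplus_sum_and_logistic(Z, W, P) - c * accu(Y % Z) +
                 0.5 * (accu(U % RU) + accu(V % RV));
    if (!std::isfinite(obj)) {
      Rcpp::stop("objective became non-finite during training; "
                 "try a smaller learning_rate");
    }
    trace.push_back(obj);
    double denom = std::max(std::fabs(obj), 2.220446049250313e-16);
    if (std::fabs(obj - obj_prev) / denom < tol) {
      converged = true;
      break;
    }
    obj_prev = obj;
    mat G = P + (c - 1.0) * (Y % P) - c * Y;
    mat dU = G * V + RU;
    mat dV = G.t() * U + RV;
    if (adagrad) {
      gU += square(dU);
      gV += square(dV);
      U -= lr * dU / sqrt(gU + eps);
      V -= lr * dV / sqrt(gV + eps);
    } else {
      U -= lr * dU;
      V -= lr * dV;
    }
  }
  return Rcpp::List::create(Rcpp::Named("U") = U,
                            Rcpp::Named("V") = V,
                            Rcpp::Named("objective_trace") = trace,
                            Rcpp::Named("converged") = converged);
}
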