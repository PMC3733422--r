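#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transition probabilities for a 2-state CTMC over time t, closed form.
static arma::mat ctmc2_prob(double q01, double q10, double t) {
  arma::mat P(2, 2);
  double lam = q01 + q10;
  if (t <= 0.0 || lam <= 0.0) {
    P.eye();
    return P;
  }
  double e = std::exp(-lam * t);
  P(0, 0) = (q10 + q01 * e) / lam;
  P(0, 1) = 1.0 - P(0, 0);
  P(1, 1) = (q01 + q10 * e) / lam;
  P(1, 0) = 1.0 - P(1, 1);
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_ctmc_prob(const arma::mat& Q, double t) {
  if (t < 0) stop("branch length must be non-negative");
  const arma::uword k = Q.n_rows;
  if (k == 2) return ctmc2_prob(Q(0, 1), Q(1, 0), t);
  arma::mat P = arma::expmat(Q * t);
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Pruning-algorithm log-likelihood of discrete tip data on a rooted tree.
//
// edge: postorder edge matrix (parent, child), 1-based node ids as in ape.
// part: (n_nodes x k) partial-likelihood matrix; tip rows hold the tip
//       indicator (ones for missing data), internal rows must be ones.
// fix_node/fix_state: 1-based; fix_node = 0 means no node is fixed.
//
// [[Rcpp::export]]
double cpp_prune_loglik(const IntegerMatrix& edge,
                        const NumericVector& elen,
                        const NumericMatrix& part_in,
                        const arma::mat& Q,
                        const NumericVector& prior,
                        int fix_node = 0,
                        int fix_state = 0) {
  const int k = Q.n_rows;
  const int n_edge = edge.nrow();
  arma::mat part(part_in.begin(), part_in.nrow(), part_in.ncol());

  if (fix_node > 0) {
    for (int s = 0; s < k; ++s)
      if (s != fix_state - 1) part(fix_node - 1, s) = 0.0;
  }

  // Eigen route for k > 2: P(t) = Re(V exp(Dt) V^-1); falls back to a
  // per-edge Pade/scaling exponential when Q is defective.
  bool use_eigen = false;
  arma::cx_vec eval;
  arma::cx_mat evec, vinv;
  if (k > 2) {
    if (arma::eig_gen(eval, evec, Q)) {
      bool ok = arma::inv(vinv, evec);
      if (ok) {
        arma::mat recon = arma::real(evec * arma::diagmat(eval) * vinv);
        double qn = arma::norm(Q, "fro");
        if (qn == 0.0 || arma::norm(recon - Q, "fro") / (qn + 1.0) < 1e-10)
          use_eigen = true;
      }
    }
  }

  const double q01 = Q(0, 1), q10 = (k == 2) ? Q(1, 0) : 0.0;
  double log_scale = 0.0;
  int root = 0;

  for (int i = 0; i < n_edge; ++i) {
    const int par = edge(i, 0) - 1;
    const int chi = edge(i, 1) - 1;
    const double t = elen[i];
    if (!std::isfinite(t) || t < 0)
      stop("non-finite or negative branch length");
    arma::mat P;
    if (k == 2) {
      P = ctmc2_prob(q01, q10, t);
    } else if (use_eigen) {
      P = arma::real(evec * arma::diagmat(arma::exp(eval * t)) * vinv);
      P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    } else {
      P = arma::expmat(Q * t);
      P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    }
    arma::vec m = P * part.row(chi).t();
    double s = arma::accu(m);
    if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
    m /= s;
    log_scale += std::log(s);
    part.row(par) %= m.t();
    root = par;
  }

  double lik = 0.0;
  for (int s = 0; s < k; ++s) lik += prior[s] * part(root, s);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}
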