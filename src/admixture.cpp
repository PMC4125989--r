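// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Binomial-mixture admixture EM.
//
// G is the N x M dosage matrix with entries 0/1/2 counting alternate
// alleles; missing entries are encoded as any negative value. Q (N x K)
// holds per-individual ancestry fractions, F (K x M) per-cluster allele
// frequencies. The updates are the classical frappe/ADMIXTURE EM; each
// one provably does not decrease
//   L = sum_{ij observed} g_ij log p_ij + (2 - g_ij) log(1 - p_ij),
//   p_ij = sum_k q_ik f_kj.
//
// F is clipped to [fmin, 1 - fmin] after every M-step so the likelihood
// stays finite for monomorphic clusters; Q rows are renormalized because
// the update preserves the simplex only in exact arithmetic and rounding
// departures are amplified across iterations. Loops run j-outer/i-inner
// to walk G and F in column-major order.

static const double FMIN = 1e-6;

// [[Rcpp::export(name = ".admixture_em_cpp")]]
Rcpp::List admixture_em_cpp(const arma::mat& G, arma::mat Q, arma::mat F,
                            double tol, int max_iter) {
  const arma::uword N = G.n_rows, M = G.n_cols, K = Q.n_cols;
  std::vector<double> trace;
  trace.reserve(64);

  arma::vec n_obs(N, arma::fill::zeros);
  for (arma::uword j = 0; j < M; ++j)
    for (arma::uword i = 0; i < N; ++i)
      if (G(i, j) >= 0) n_obs(i) += 1.0;

  double ll_old = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;

  arma::mat Qnum(N, K);
  std::vector<double> qf(K), fnum(K), fden(K);

  for (iter = 1; iter <= max_iter; ++iter) {
    Qnum.zeros();
    double ll = 0.0;

    for (arma::uword j = 0; j < M; ++j) {
      const double* gj = G.colptr(j);
      double* fj = F.colptr(j);
      for (arma::uword k = 0; k < K; ++k) {
        fnum[k] = 0.0;
        fden[k] = 0.0;
      }
      for (arma::uword i = 0; i < N; ++i) {
        const double g = gj[i];
        if (g < 0) continue;
        double p = 0.0;
        for (arma::uword k = 0; k < K; ++k) {
          qf[k] = Q(i, k) * fj[k];
          p += qf[k];
        }
        // F is clipped to [FMIN, 1 - FMIN], so p lies in that range up to
        // rounding; guard the logs but keep the raw p in the posterior
        // weights so they sum exactly to one (keeps EM monotone).
        const double pl = std::min(std::max(p, FMIN), 1.0 - FMIN);
        ll += g * std::log(pl) + (2.0 - g) * std::log(1.0 - pl);
        const double invp = g / p;
        const double inv1p = (2.0 - g) / (1.0 - p);
        for (arma::uword k = 0; k < K; ++k) {
          const double alt_k = qf[k] * invp;                 // g * a_k
          const double ref_k = (Q(i, k) - qf[k]) * inv1p;    // (2-g) * b_k
          Qnum(i, k) += alt_k + ref_k;
          fnum[k] += alt_k;
          fden[k] += alt_k + ref_k;
        }
      }
      for (arma::uword k = 0; k < K; ++k) {
        double f = fden[k] > 0 ? fnum[k] / fden[k] : fj[k];
        if (f < FMIN) f = FMIN;
        if (f > 1.0 - FMIN) f = 1.0 - FMIN;
        fj[k] = f;
      }
    }
    trace.push_back(ll);

    for (arma::uword i = 0; i < N; ++i) {
      if (n_obs(i) > 0) {
        double rs = 0.0;
        for (arma::uword k = 0; k < K; ++k) rs += Qnum(i, k);
        for (arma::uword k = 0; k < K; ++k) Q(i, k) = Qnum(i, k) / rs;
      } else {
        for (arma::uword k = 0; k < K; ++k) Q(i, k) = 1.0 / (double)K;
      }
    }

    if (std::isfinite(ll_old) && ll - ll_old < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
  }

  // log-likelihood at the final parameter values
  double ll_final = 0.0;
  for (arma::uword j = 0; j < M; ++j) {
    const double* gj = G.colptr(j);
    const double* fj = F.colptr(j);
    for (arma::uword i = 0; i < N; ++i) {
      const double g = gj[i];
      if (g < 0) continue;
      double p = 0.0;
      for (arma::uword k = 0; k < K; ++k) p += Q(i, k) * fj[k];
      p = std::min(std::max(p, FMIN), 1.0 - FMIN);
      ll_final += g * std::log(p) + (2.0 - g) * std::log(1.0 - p);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("Q") = Q, Rcpp::Named("F") = F,
      Rcpp::Named("loglik") = ll_final,
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("n_iter") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged);
}
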