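// EM for the admixture likelihood
//   L(Q, F) = sum_ij obs_ij * [ g_ij * log(sum_k q_ik f_kj)
//                             + (2 - g_ij) * log(sum_k q_ik (1 - f_kj)) ]
// with diploid dosages g in {0,1,2}, ancestry proportions Q (n x K, rows on
// the simplex) and cluster allele frequencies F (K x L).  Missing genotypes
// carry obs_ij = 0 and contribute nothing.  The updates are the standard
// multiplicative EM steps; both blocks are updated from the old parameters,
// so the log-likelihood is non-decreasing.  The log-likelihood itself is
// only evaluated every `ll_every` iterations (the logs dominate the cost of
// an iteration); `tol` is the per-iteration relative change declaring
// convergence.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double admix_loglik(const mat& G1, const mat& G2, const mat& P) {
  return accu(G1 % log(P) + G2 % log(1.0 - P));
}

// [[Rcpp::export]]
Rcpp::List admix_em_cpp(const arma::mat& G, const arma::mat& obs,
                        arma::mat Q, arma::mat F,
                        double tol, int max_iter, double f_eps,
                        int ll_every = 5) {
  const double p_eps = 1e-12;
  const mat G1 = G % obs;            // observed reference-allele counts
  const mat G2 = (2.0 - G) % obs;    // observed alternate-allele counts
  const vec denom = 2.0 * sum(obs, 1);  // 2 * (loci observed) per individual

  std::vector<double> ll;
  ll.reserve(max_iter / ll_every + 2);
  mat P = clamp(Q * F, p_eps, 1.0 - p_eps);
  ll.push_back(admix_loglik(G1, G2, P));
  bool converged = false;
  int it;

  for (it = 1; it <= max_iter; ++it) {
    const mat R = G1 / P;
    const mat S = G2 / (1.0 - P);

    mat Fnum = F % (Q.t() * R);                    // K x L
    mat Fden = Fnum + (1.0 - F) % (Q.t() * S);
    // loci with no observed data in any individual keep their old value
    const uvec dead = find(Fden <= 0);
    Fden.elem(dead).ones();
    Fnum.elem(dead) = F.elem(dead);
    mat Fnew = clamp(Fnum / Fden, f_eps, 1.0 - f_eps);

    mat Qnew = Q % (R * F.t() + S * (1.0 - F).t());
    Qnew.each_col() /= denom;
    const vec rs = sum(Qnew, 1);                   // exact 1 up to rounding
    Qnew.each_col() /= rs;

    Q = std::move(Qnew);
    F = std::move(Fnew);
    P = clamp(Q * F, p_eps, 1.0 - p_eps);

    if (it % ll_every == 0 || it == max_iter) {
      const double l = admix_loglik(G1, G2, P);
      if (!std::isfinite(l))
        Rcpp::stop("non-finite log-likelihood at iteration %d", it);
      const double prev = ll.back();
      ll.push_back(l);
      if (std::abs(l - prev) < tol * ll_every * std::abs(l)) {
        converged = true;
        break;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("Q") = Q,
    Rcpp::Named("F") = F,
    Rcpp::Named("loglik_trace") = ll,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = std::min(it, max_iter));
}
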