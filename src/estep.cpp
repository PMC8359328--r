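// Quadrature E-step kernels shared by all model variants.
//
// Conventions: scores are 0-based category codes, -1 = missing.
// logP is a C x Q x K cube of log category probabilities per item at the
// quadrature nodes; logw is the length-Q vector of log prior weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Posterior over the node grid for one person, written into `post`.
// Returns the person's marginal log-likelihood.
static double person_posterior(const imat& scores, const cube& logP,
                               const vec& logw, uword j, vec& post) {
  const uword K = scores.n_cols;
  post = logw;
  for (uword k = 0; k < K; ++k) {
    int s = scores(j, k);
    if (s < 0) continue;
    const mat& slab = logP.slice(k);
    for (uword q = 0; q < post.n_elem; ++q) post(q) += slab((uword)s, q);
  }
  double m = post.max();
  post = exp(post - m);
  double tot = accu(post);
  post /= tot;
  return m + std::log(tot);
}

// [[Rcpp::export]]
Rcpp::List estep_counts_cpp(const arma::imat& scores, const arma::cube& logP,
                            const arma::vec& logw) {
  const uword N = scores.n_rows, K = scores.n_cols;
  const uword C = logP.n_rows, Q = logP.n_cols;
  cube counts(C, Q, K, fill::zeros);
  vec nbar(Q, fill::zeros);
  double ll = 0.0;
  vec post(Q);
  for (uword j = 0; j < N; ++j) {
    ll += person_posterior(scores, logP, logw, j, post);
    nbar += post;
    for (uword k = 0; k < K; ++k) {
      int s = scores(j, k);
      if (s < 0) continue;
      counts.slice(k).row((uword)s) += post.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("nbar") = nbar,
                            Rcpp::Named("counts") = counts);
}

// [[Rcpp::export]]
double marginal_loglik_cpp(const arma::imat& scores, const arma::cube& logP,
                           const arma::vec& logw) {
  const uword N = scores.n_rows;
  double ll = 0.0;
  vec post(logw.n_elem);
  for (uword j = 0; j < N; ++j)
    ll += person_posterior(scores, logP, logw, j, post);
  return ll;
}

// Posterior moments of the latent variables per person: EAP means,
// posterior variances (and the per-person marginal log-likelihood).
// Theta is Q x D (node coordinates).
// [[Rcpp::export]]
Rcpp::List eap_moments_cpp(const arma::imat& scores, const arma::cube& logP,
                           const arma::vec& logw, const arma::mat& Theta) {
  const uword N = scores.n_rows, D = Theta.n_cols, Q = Theta.n_rows;
  mat eap(N, D), pvar(N, D);
  vec ll(N);
  vec post(Q);
  const mat Theta2 = square(Theta);
  for (uword j = 0; j < N; ++j) {
    ll(j) = person_posterior(scores, logP, logw, j, post);
    for (uword d = 0; d < D; ++d) {
      double m1 = dot(post, Theta.col(d));
      double m2 = dot(post, Theta2.col(d));
      eap(j, d) = m1;
      pvar(j, d) = std::max(m2 - m1 * m1, 0.0);
    }
  }
  return Rcpp::List::create(Rcpp::Named("eap") = eap,
                            Rcpp::Named("pvar") = pvar,
                            Rcpp::Named("loglik") = ll);
}
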