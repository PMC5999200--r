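#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the conditional GSI mixture model.
//
// logL:  N x C matrix of per-individual log-likelihoods given each baseline
//        collection (allele frequencies held at their posterior means).
// alpha: length-C Dirichlet prior on the mixing proportions pi.
//
// Alternates z_i | pi  ~ Categorical( pi_c * L_ic )  and
//            pi | z    ~ Dirichlet( alpha + n(z) ).
// Returns the retained pi trace (post burn-in) and the Rao-Blackwellized
// per-individual membership posterior, i.e. the average over retained
// sweeps of Pr(z_i = c | pi_t, y_i).
// [[Rcpp::export]]
List gibbs_mixture_cpp(NumericMatrix logL, NumericVector alpha,
                       int n_iter, int burn_in) {
  const int N = logL.nrow(), C = logL.ncol();
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");

  // row-scaled likelihoods (per-row constant cancels in the posterior)
  NumericMatrix L(N, C);
  for (int i = 0; i < N; ++i) {
    double m = logL(i, 0);
    for (int c = 1; c < C; ++c) if (logL(i, c) > m) m = logL(i, c);
    for (int c = 0; c < C; ++c) L(i, c) = std::exp(logL(i, c) - m);
  }

  RNGScope scope;
  std::vector<double> pi(C);
  double asum = 0.0;
  for (int c = 0; c < C; ++c) asum += alpha[c];
  for (int c = 0; c < C; ++c) pi[c] = alpha[c] / asum;

  const int keep = n_iter - burn_in;
  NumericMatrix pi_trace(keep, C);
  NumericMatrix post(N, C);
  std::vector<int> zcount(C);
  std::vector<double> w(C);

  for (int t = 0; t < n_iter; ++t) {
    std::fill(zcount.begin(), zcount.end(), 0);
    const bool retain = t >= burn_in;
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { w[c] = pi[c] * L(i, c); tot += w[c]; }
      double u = unif_rand() * tot, cum = 0.0;
      int z = C - 1;
      for (int c = 0; c < C; ++c) {
        cum += w[c];
        if (u <= cum) { z = c; break; }
      }
      ++zcount[z];
      if (retain) {
        for (int c = 0; c < C; ++c) post(i, c) += w[c] / tot;
      }
    }
    double g, gsum = 0.0;
    for (int c = 0; c < C; ++c) {
      g = R::rgamma(alpha[c] + zcount[c], 1.0);
      pi[c] = g; gsum += g;
    }
    for (int c = 0; c < C; ++c) pi[c] /= gsum;
    if (retain) {
      for (int c = 0; c < C; ++c) pi_trace(t - burn_in, c) = pi[c];
    }
  }
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) post(i, c) /= keep;

  return List::create(_["pi_trace"] = pi_trace, _["posterior"] = post);
}
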