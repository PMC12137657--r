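// STRUCTURE-style admixture model with uncorrelated allele frequencies.
//
// Each of the two allele copies of individual i at locus l carries a
// latent cluster label sampled by Gibbs from q_i x the cluster's allele
// frequency; cluster frequencies get Beta(1,1) priors and individual
// admixture proportions a symmetric Dirichlet(alpha) prior. Missing
// genotypes (coded < 0) are skipped. Uses R's RNG.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".admixture_chain_cpp")]]
List admixture_chain_cpp(IntegerMatrix calls, int K, int n_burn,
                         int n_iter, double alpha_q) {
  const int n = calls.nrow();
  const int L = calls.ncol();

  // allele copies per (i, l): genotype g -> copies {1,...} with g alt
  // latent labels z1, z2 per (i, l)
  IntegerMatrix z1(n, L), z2(n, L);
  NumericMatrix q(n, K);            // admixture proportions
  NumericMatrix p(K, L);            // alt-allele frequency per cluster
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p(k, l) = R::runif(0.2, 0.8);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      z1(i, l) = (int)std::floor(R::runif(0, K));
      z2(i, l) = (int)std::floor(R::runif(0, K));
    }

  NumericMatrix q_mean(n, K);
  double lnl_sum = 0.0;
  int n_kept = 0;
  std::vector<double> w(K);

  for (int iter = 0; iter < n_burn + n_iter; ++iter) {
    // counts for conjugate updates
    NumericMatrix n_alt(K, L), n_ref(K, L);
    NumericMatrix n_ik(n, K);

    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = calls(i, l);
        if (g < 0) continue;
        // copy alleles: g alt copies, 2-g ref copies
        for (int c = 0; c < 2; ++c) {
          int allele = (c < g) ? 1 : 0;
          double wsum = 0;
          for (int k = 0; k < K; ++k) {
            double pf = allele ? p(k, l) : 1.0 - p(k, l);
            w[k] = q(i, k) * pf;
            wsum += w[k];
          }
          double u = R::runif(0.0, wsum);
          int pick = K - 1;
          double acc = 0;
          for (int k = 0; k < K; ++k) {
            acc += w[k];
            if (u <= acc) { pick = k; break; }
          }
          if (c == 0) z1(i, l) = pick; else z2(i, l) = pick;
          if (allele) n_alt(pick, l) += 1; else n_ref(pick, l) += 1;
          n_ik(i, pick) += 1;
        }
      }
    }

    // frequencies: Beta(1 + n_alt, 1 + n_ref)
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        p(k, l) = R::rbeta(1.0 + n_alt(k, l), 1.0 + n_ref(k, l));

    // admixture: Dirichlet(alpha + n_ik)
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha_q + n_ik(i, k), 1.0);
        q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) q(i, k) /= s;
    }

    if (iter >= n_burn) {
      n_kept++;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) q_mean(i, k) += q(i, k);
      // observed-data log likelihood under current (q, p)
      double lnl = 0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
          int g = calls(i, l);
          if (g < 0) continue;
          double pi = 0;
          for (int k = 0; k < K; ++k) pi += q(i, k) * p(k, l);
          if (pi < 1e-12) pi = 1e-12;
          if (pi > 1 - 1e-12) pi = 1 - 1e-12;
          double ll = (g == 1)
            ? std::log(2.0) + std::log(pi) + std::log(1 - pi)
            : (g == 2 ? 2.0 * std::log(pi) : 2.0 * std::log(1 - pi));
          lnl += ll;
        }
      lnl_sum += lnl;
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_mean(i, k) /= n_kept;

  return List::create(_["q"] = q_mean,
                      _["mean_lnl"] = lnl_sum / n_kept);
}
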