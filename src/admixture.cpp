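#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the haploid-band admixture model:
//   Z_il | q_i       ~ Categorical(q_i)
//   X_il | Z_il = k  ~ Bernoulli(F_kl)
//   F_kl ~ Beta(lam1, lam2),  q_i ~ Dirichlet(alpha)
// Conjugate updates throughout; the recorded lnL is the marginal
// log-likelihood sum_il log sum_k q_ik P(x_il | F_kl) (Z integrated out),
// which is the per-iteration normalizer of the Z draw. Missing cells
// (NA) contribute nothing to counts or likelihood. Uses R's RNG, so a
// set.seed() before the call makes the run bit-reproducible.

static inline double clampp(double x) {
  if (x < 1e-12) return 1e-12;
  if (x > 1.0 - 1e-12) return 1.0 - 1e-12;
  return x;
}

// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix X, int K, double alpha,
                     double lam1, double lam2,
                     int burn_in, int reps, bool sample_alpha) {
  const int n = X.nrow(), L = X.ncol();
  const int total = burn_in + reps;
  NumericMatrix F(K, L), Q(n, K);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      F(k, l) = clampp(R::rbeta(lam1, lam2));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      Q(i, k) = 1.0 / K;

  NumericMatrix n1(K, L), n0(K, L), cnt(n, K);
  NumericMatrix Qsum(n, K), Fsum(K, L);
  NumericVector lnL_trace(reps);
  std::vector<double> pk(K);

  for (int it = 0; it < total; ++it) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double lnL = 0.0;

    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int x = X(i, l);
        if (x == NA_INTEGER) continue;
        double norm = 0.0;
        for (int k = 0; k < K; ++k) {
          double lik = x ? F(k, l) : 1.0 - F(k, l);
          pk[k] = Q(i, k) * lik;
          norm += pk[k];
        }
        lnL += std::log(norm);
        double u = R::unif_rand() * norm, acc = 0.0;
        int z = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += pk[k];
          if (u <= acc) { z = k; break; }
        }
        if (x) n1(z, l) += 1.0; else n0(z, l) += 1.0;
        cnt(i, z) += 1.0;
      }
    }

    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        F(k, l) = clampp(R::rbeta(lam1 + n1(k, l), lam2 + n0(k, l)));

    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cnt(i, k), 1.0);
        Q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) = clampp(Q(i, k) / s);
    }

    if (sample_alpha && K > 1) {
      // random-walk Metropolis on log(alpha), Uniform(0, 10) prior
      double prop = alpha * std::exp(R::norm_rand() * 0.3);
      if (prop > 0.0 && prop < 10.0) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        double lp = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                    (prop - 1.0) * slq;
        double lc = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                    (alpha - 1.0) * slq;
        double lr = lp - lc + std::log(prop) - std::log(alpha);
        if (std::log(R::unif_rand()) < lr) alpha = prop;
      }
    }

    if (it >= burn_in) {
      lnL_trace[it - burn_in] = lnL;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Fsum(k, l) += F(k, l);
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= reps;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Fsum(k, l) /= reps;

  return List::create(_["Q"] = Qsum, _["F"] = Fsum,
                      _["lnL"] = lnL_trace, _["alpha"] = alpha);
}
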