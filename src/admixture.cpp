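#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the standard admixture model (independent allele
// frequencies): cluster allele frequencies P ~ Beta(lambda, lambda) prior,
// per-accession ancestry Q ~ Dirichlet(alpha). Each sweep samples the
// cluster of origin of every allele copy (Z), then P and Q from their
// conditional posteriors. Missing genotypes are skipped entirely. Uses R's
// RNG so set.seed() in R fixes the run.
//
// G is an N x L integer matrix of alt-allele dosages with NA for missing.

static inline double clamp01(double x) {
  const double eps = 1e-12;
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix G, int K, int burnin, int iterations,
                         double alpha, double lambda) {
  const int N = G.nrow(), L = G.ncol();
  RNGScope scope;

  NumericMatrix P(L, K);      // alt-allele frequency per locus x cluster
  NumericMatrix Q(N, K);      // ancestry per accession x cluster
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k) P(l, k) = R::runif(0.05, 0.95);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  NumericMatrix Qsum(N, K), Psum(L, K);
  NumericVector trace(iterations);

  std::vector<double> prob(K), nalt(L * K), nref(L * K), m(N * K);
  const int sweeps = burnin + iterations;

  for (int sweep = 0; sweep < sweeps; ++sweep) {
    std::fill(nalt.begin(), nalt.end(), 0.0);
    std::fill(nref.begin(), nref.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);

    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const int g = G(i, l);
        if (g == NA_INTEGER) continue;
        // copies: (2 - g) ref copies, g alt copies
        for (int copy = 0; copy < 2; ++copy) {
          const bool is_alt = copy < g;  // g=1 -> one alt, one ref
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            const double pf = is_alt ? P(l, k) : 1.0 - P(l, k);
            prob[k] = Q(i, k) * pf;
            tot += prob[k];
          }
          double u = R::unif_rand() * tot;
          int k = 0;
          for (; k < K - 1; ++k) {
            u -= prob[k];
            if (u <= 0.0) break;
          }
          if (is_alt) nalt[l * K + k] += 1.0;
          else        nref[l * K + k] += 1.0;
          m[i * K + k] += 1.0;
        }
      }
    }

    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k)
        P(l, k) = R::rbeta(lambda + nalt[l * K + k], lambda + nref[l * K + k]);

    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = R::rgamma(alpha + m[i * K + k], 1.0);
        prob[k] = d;
        tot += d;
      }
      for (int k = 0; k < K; ++k) Q(i, k) = prob[k] / tot;
    }

    if (sweep >= burnin) {
      // log-likelihood of the data at the current (P, Q)
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int l = 0; l < L; ++l) {
          const int g = G(i, l);
          if (g == NA_INTEGER) continue;
          double u = 0.0;
          for (int k = 0; k < K; ++k) u += Q(i, k) * P(l, k);
          u = clamp01(u);
          if (g == 0)      ll += 2.0 * std::log(1.0 - u);
          else if (g == 2) ll += 2.0 * std::log(u);
          else             ll += std::log(2.0 * u * (1.0 - u));
        }
      }
      const int it = sweep - burnin;
      trace[it] = ll;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k) Psum(l, k) += P(l, k);
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= iterations;
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k) Psum(l, k) /= iterations;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["trace"] = trace);
}
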