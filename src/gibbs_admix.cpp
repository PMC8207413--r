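#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent Dirichlet
// cluster allele frequencies (lambda prior) and Dirichlet(alpha)
// ancestry rows. Allele data are integer state indices per locus
// (1..n_alleles[l]; 0 = missing), one matrix per allele copy.
//
// Each sweep: (i) sample the cluster-of-origin of every allele copy
// with probability proportional to q_ik * p_k(allele); (ii) resample Q
// rows from Dirichlet(alpha + origin counts); (iii) resample P rows
// from Dirichlet(lambda + allele counts). The log-likelihood
// sum log(sum_k q_ik p_k(a)) is recorded each sweep; reported Q and P
// are posterior means over the kept sweeps.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_admix_cpp(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector n_alleles, int K,
                     double alpha, double lambda,
                     int burnin, int sweeps) {
  const int n = a1.nrow(), L = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (sweeps < 1) stop("at least one post-burn-in sweep is required");

  // state
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  std::vector<NumericMatrix> P(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, n_alleles[l]);
    std::fill(P[l].begin(), P[l].end(), 1.0 / n_alleles[l]);
  }

  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, n_alleles[l]);
  NumericVector lnl(sweeps);

  IntegerMatrix cntQ(n, K);
  std::vector<NumericMatrix> cntP(L);
  for (int l = 0; l < L; ++l) cntP[l] = NumericMatrix(K, n_alleles[l]);
  std::vector<double> w(K);

  const int total = burnin + sweeps;
  for (int s = 0; s < total; ++s) {
    std::fill(cntQ.begin(), cntQ.end(), 0);
    for (int l = 0; l < L; ++l)
      std::fill(cntP[l].begin(), cntP[l].end(), 0.0);

    // (i) origins
    for (int l = 0; l < L; ++l) {
      NumericMatrix &Pl = P[l];
      for (int copy = 0; copy < 2; ++copy) {
        IntegerMatrix &A = (copy == 0) ? a1 : a2;
        for (int i = 0; i < n; ++i) {
          int a = A(i, l);
          if (a <= 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * Pl(k, a - 1);
            tot += w[k];
          }
          double u = unif_rand() * tot;
          int k = 0;
          double acc = w[0];
          while (k < K - 1 && u > acc) acc += w[++k];
          cntQ(i, k) += 1;
          cntP[l](k, a - 1) += 1.0;
        }
      }
    }

    // (ii) Q rows ~ Dirichlet(alpha + counts)
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ(i, k), 1.0);
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }

    // (iii) P rows ~ Dirichlet(lambda + counts)
    for (int l = 0; l < L; ++l) {
      NumericMatrix &Pl = P[l];
      const int A = n_alleles[l];
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int a = 0; a < A; ++a) {
          double g = R::rgamma(lambda + cntP[l](k, a), 1.0);
          Pl(k, a) = g;
          tot += g;
        }
        for (int a = 0; a < A; ++a) Pl(k, a) /= tot;
      }
    }

    // log-likelihood of the current state
    double ll = 0.0;
    for (int l = 0; l < L; ++l) {
      NumericMatrix &Pl = P[l];
      for (int copy = 0; copy < 2; ++copy) {
        IntegerMatrix &A = (copy == 0) ? a1 : a2;
        for (int i = 0; i < n; ++i) {
          int a = A(i, l);
          if (a <= 0) continue;
          double m = 0.0;
          for (int k = 0; k < K; ++k) m += Q(i, k) * Pl(k, a - 1);
          ll += std::log(m);
        }
      }
    }

    if (s >= burnin) {
      lnl[s - burnin] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < n_alleles[l]; ++a)
            Psum[l](k, a) += P[l](k, a);
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= sweeps;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a) Psum[l](k, a) /= sweeps;
    Pout[l] = Psum[l];
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout, _["lnl"] = lnl);
}
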