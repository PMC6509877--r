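#include <Rcpp.h>
using namespace Rcpp;

// Genotypes for one panel: individuals x SNPs matrix of 0/1/2 counts.
// freqs is SNPs x K ("1"-allele frequency per population), pop is the
// 1-based population index per individual. Each genotype is the sum of
// two Bernoulli(f) draws (HWE within population), using R's RNG stream.
// [[Rcpp::export(name = ".panel_genotypes_cpp")]]
IntegerMatrix panel_genotypes_cpp(NumericMatrix freqs, IntegerVector pop) {
  const int n = pop.size(), m = freqs.nrow(), K = freqs.ncol();
  IntegerMatrix G(n, m);
  std::vector<double> f(K);
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < K; ++k) f[k] = freqs(j, k);
    int *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      const double p = f[pop[i] - 1];
      col[i] = (unif_rand() < p) + (unif_rand() < p);
    }
  }
  return G;
}

// Center each SNP column and divide by sqrt(ptilde (1 - ptilde)) with the
// pseudo-count frequency estimate ptilde = (1 + colsum) / (2 + 2n).
// [[Rcpp::export(name = ".standardize_cpp")]]
List standardize_cpp(IntegerMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  NumericMatrix X(n, m);
  NumericVector ptilde(m);
  for (int j = 0; j < m; ++j) {
    const int *col = &G(0, j);
    long s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    const double pt = (1.0 + s) / (2.0 + 2.0 * n);
    ptilde[j] = pt;
    const double ctr = (double)s / n;
    const double sc = std::sqrt(pt * (1.0 - pt));
    double *out = &X(0, j);
    for (int i = 0; i < n; ++i) out[i] = (col[i] - ctr) / sc;
  }
  return List::create(_["standardized"] = X, _["est_freq"] = ptilde);
}
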