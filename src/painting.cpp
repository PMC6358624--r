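#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-backward expected copying under the Li-and-Stephens haplotype
// copying model for one recipient haplotype against a set of donor columns.
//
// geno: L x H 0/1 matrix (all haplotypes); chrom: integer chromosome index
// per SNP (1..C, contiguous blocks); cm: cumulative cM within chromosome.
// Transitions between adjacent SNPs at distance d cM: stay with probability
// exp(-rho*d), otherwise jump to a uniformly chosen donor (self included).
// Emission: 1-theta on allele match, theta on mismatch. Expected copied
// length attributes each inter-SNP interval to the posterior at its left
// SNP. Donor alleles are staged into a donor-major buffer so all inner
// loops are stride-1.
//
// Returns per-donor, per-chromosome expected lengths (cM); optionally
// expected chunk counts and the per-SNP posterior aggregated over donor
// groups (for coancestry curves).
// [[Rcpp::export]]
List cp_paint_hap_cpp(const IntegerMatrix& geno, const IntegerVector& chrom,
                      const NumericVector& cm, int hap_col,
                      const IntegerVector& donor_cols, double rho, double theta,
                      bool want_counts, const IntegerVector& donor_group,
                      int n_group, bool want_posterior) {
  const int L = geno.nrow();
  const int D = donor_cols.size();
  if (D < 1) stop("empty donor set");
  int C = 0;
  for (int j = 0; j < L; j++) if (chrom[j] > C) C = chrom[j];

  NumericMatrix len(D, C);
  NumericMatrix cnt(want_counts ? D : 1, want_counts ? C : 1);
  NumericMatrix post(want_posterior ? L : 1, want_posterior ? n_group : 1);

  // stage donor alleles donor-major: G[d + D*j]
  std::vector<signed char> G((size_t)D * L);
  for (int d = 0; d < D; d++) {
    const int col = donor_cols[d];
    for (int j = 0; j < L; j++) G[d + (size_t)D * j] = (signed char)geno(j, col);
  }
  std::vector<signed char> hap(L);
  for (int j = 0; j < L; j++) hap[j] = (signed char)geno(j, hap_col);

  std::vector<double> a(D), b(D), e(D), gamma(D);
  std::vector<double> af;   // scaled forward variables, af[d + D*j] per chrom
  std::vector<double> cs;

  int start = 0;
  while (start < L) {
    const int cc = chrom[start];
    int end = start;
    while (end < L && chrom[end] == cc) end++;
    const int n = end - start;

    af.assign((size_t)D * n, 0.0);
    cs.assign(n, 0.0);

    double s = 0.0;
    {
      const signed char h0 = hap[start];
      const signed char* g = &G[(size_t)D * start];
      for (int d = 0; d < D; d++) {
        a[d] = ((h0 == g[d]) ? 1.0 - theta : theta) / D;
        s += a[d];
      }
    }
    cs[0] = s;
    for (int d = 0; d < D; d++) { a[d] /= s; af[d] = a[d]; }

    for (int j = 1; j < n; j++) {
      const double r = std::exp(-rho * (cm[start + j] - cm[start + j - 1]));
      const double mix = (1.0 - r) / D;
      const signed char hj = hap[start + j];
      const signed char* g = &G[(size_t)D * (start + j)];
      double* afj = &af[(size_t)D * j];
      s = 0.0;
      for (int d = 0; d < D; d++) {
        const double em = (hj == g[d]) ? 1.0 - theta : theta;
        const double v = em * (r * a[d] + mix);
        afj[d] = v;
        s += v;
      }
      cs[j] = s;
      const double inv = 1.0 / s;
      for (int d = 0; d < D; d++) { afj[d] *= inv; a[d] = afj[d]; }
    }

    for (int d = 0; d < D; d++) b[d] = 1.0;
    for (int j = n - 1; j >= 0; j--) {
      const double* afj = &af[(size_t)D * j];
      double gs = 0.0;
      for (int d = 0; d < D; d++) { gamma[d] = afj[d] * b[d]; gs += gamma[d]; }
      const double ginv = 1.0 / gs;
      for (int d = 0; d < D; d++) gamma[d] *= ginv;

      if (j < n - 1) {
        const double dlen = cm[start + j + 1] - cm[start + j];
        double* lc = &len(0, cc - 1);
        for (int d = 0; d < D; d++) lc[d] += dlen * gamma[d];
      }
      if (want_posterior) {
        for (int d = 0; d < D; d++) post(start + j, donor_group[d] - 1) += gamma[d];
      }
      if (want_counts && j == 0) {
        double* cc0 = &cnt(0, cc - 1);
        for (int d = 0; d < D; d++) cc0[d] += gamma[d];
      }

      if (j > 0) {
        const double r = std::exp(-rho * (cm[start + j] - cm[start + j - 1]));
        const double mix = (1.0 - r) / D;
        const signed char hj = hap[start + j];
        const signed char* g = &G[(size_t)D * (start + j)];
        double sum_eb = 0.0;
        for (int d = 0; d < D; d++) {
          const double em = (hj == g[d]) ? 1.0 - theta : theta;
          e[d] = em * b[d];
          sum_eb += e[d];
        }
        if (want_counts) {
          // expected new chunks entering donor d at SNP j:
          // gamma_j(d) - P(S_{j-1} = d, S_j = d)
          const double* afp = &af[(size_t)D * (j - 1)];
          const double icj = 1.0 / cs[j];
          double* cc0 = &cnt(0, cc - 1);
          for (int d = 0; d < D; d++) {
            double nc = gamma[d] - afp[d] * (r + mix) * e[d] * icj;
            if (nc > 0) cc0[d] += nc;
          }
        }
        const double icj = 1.0 / cs[j];
        for (int d = 0; d < D; d++)
          b[d] = (r * e[d] + mix * sum_eb) * icj;
      }
    }
    start = end;
  }

  List out = List::create(_["lengths"] = len);
  if (want_counts) out["counts"] = cnt;
  if (want_posterior) out["posterior"] = post;
  return out;
}
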