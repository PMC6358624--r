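#include <Rcpp.h>
using namespace Rcpp;

// Accumulate binned cross-products of per-SNP donor-group copying
// posteriors for one haplotype: for every within-chromosome position pair
// (j, k) whose genetic distance falls in [min_cm, max_cm), add
// z_j z_k^T into the distance bin. Bin counts depend only on the map, so
// they are returned alongside. Curves (ancestry covariance vs distance)
// are assembled in R by pooling these sums over haplotypes.
// [[Rcpp::export]]
List curve_accum_cpp(const NumericMatrix& post, const IntegerVector& chrom,
                     const NumericVector& cm, double bin_width,
                     double min_cm, double max_cm) {
  const int L = post.nrow();
  const int G = post.ncol();
  const int nbin = (int)std::ceil((max_cm - min_cm) / bin_width);
  if (nbin < 1) stop("empty bin range");
  NumericVector sums(G * G * nbin);     // [a + G*b + G*G*bin]
  NumericVector cnt(nbin);

  int start = 0;
  while (start < L) {
    const int cc = chrom[start];
    int end = start;
    while (end < L && chrom[end] == cc) end++;
    for (int j = start; j < end; j++) {
      for (int k = j + 1; k < end; k++) {
        const double d = cm[k] - cm[j];
        if (d < min_cm) continue;
        if (d >= max_cm) break;
        const int bin = (int)((d - min_cm) / bin_width);
        cnt[bin] += 1.0;
        double* s = &sums[(size_t)G * G * bin];
        for (int b = 0; b < G; b++) {
          const double zk = post(k, b);
          if (zk == 0.0) continue;
          for (int a = 0; a < G; a++)
            s[a + G * b] += post(j, a) * zk;
        }
      }
    }
    start = end;
  }
  return List::create(_["sums"] = sums, _["counts"] = cnt, _["n_bin"] = nbin);
}
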