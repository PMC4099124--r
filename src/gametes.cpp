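#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Recombinant gametes under a Haldane map (no interference): the number of
// crossovers per chromosome is Poisson(length in Morgans), crossover
// positions are uniform on the chromosome. Gamete k is a mosaic of
// haplotype rows row_a[k], row_b[k] (1-based) of `haps`, starting from a
// randomly chosen strand. Uses R's RNG so results are governed by set.seed().
//
// chr_start/chr_end: 1-based first/last marker index of each chromosome
// (markers ordered by chromosome then position); pos_m: marker positions in
// Morgans within their chromosome; chr_len: chromosome lengths in Morgans.
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& haps,
                               const IntegerVector& row_a,
                               const IntegerVector& row_b,
                               const IntegerVector& chr_start,
                               const IntegerVector& chr_end,
                               const NumericVector& pos_m,
                               const NumericVector& chr_len) {
  const int n_gam = row_a.size();
  const int m = haps.ncol();
  const int n_chr = chr_start.size();
  IntegerMatrix out(n_gam, m);
  std::vector<double> xo;

  for (int k = 0; k < n_gam; ++k) {
    const int ra = row_a[k] - 1;
    const int rb = row_b[k] - 1;
    for (int c = 0; c < n_chr; ++c) {
      const double L = chr_len[c];
      const int nx = (int) R::rpois(L);
      xo.resize(nx);
      for (int j = 0; j < nx; ++j) xo[j] = unif_rand() * L;
      std::sort(xo.begin(), xo.end());
      bool use_a = unif_rand() < 0.5;
      int jx = 0;
      for (int i = chr_start[c] - 1; i < chr_end[c]; ++i) {
        while (jx < nx && xo[jx] < pos_m[i]) { use_a = !use_a; ++jx; }
        out(k, i) = use_a ? haps(ra, i) : haps(rb, i);
      }
    }
  }
  return out;
}
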