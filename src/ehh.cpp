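#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity along one flank of a core site.
//
// H: haplotype matrix (haplotypes x sites, 0/1); core: 0-based core column;
// carriers: 0-based row indices of the haplotypes carrying the core allele
// (or all haplotypes for the combined curve); dir: +1 right, -1 left.
// Walks outward refining the partition of carriers into identical extended
// haplotypes; EHH(x) = sum_g C(e_g, 2) / C(n_c, 2). Emits one value per
// flanking site and stops after the first value below `cutoff` (that value
// is included so the caller can decide how to truncate).
// [[Rcpp::export]]
NumericVector ehh_side_cpp(const IntegerMatrix& H, int core,
                           const IntegerVector& carriers, double cutoff,
                           int dir) {
  const int nc = carriers.size();
  const int M = H.ncol();
  const double denom = nc * (nc - 1) / 2.0;
  std::vector<int> grp(nc);
  std::vector<double> out;
  if (nc < 2) return NumericVector(0);
  // haplotype identity includes the core-site allele, so the partition
  // starts split by it (a single group when following one core allele)
  int ngrp = 0;
  {
    int seen[2] = {-1, -1};
    for (int i = 0; i < nc; ++i) {
      int a = H(carriers[i], core) != 0 ? 1 : 0;
      if (seen[a] < 0) seen[a] = ngrp++;
      grp[i] = seen[a];
    }
  }
  for (int j = core + dir; j >= 0 && j < M; j += dir) {
    std::vector<int> lookup(2 * ngrp, -1);
    int nnew = 0;
    for (int i = 0; i < nc; ++i) {
      int allele = H(carriers[i], j) != 0 ? 1 : 0;
      int key = 2 * grp[i] + allele;
      if (lookup[key] < 0) lookup[key] = nnew++;
      grp[i] = lookup[key];
    }
    ngrp = nnew;
    std::vector<int> cnt(ngrp, 0);
    for (int i = 0; i < nc; ++i) cnt[grp[i]]++;
    double num = 0.0;
    for (int g = 0; g < ngrp; ++g) num += cnt[g] * (cnt[g] - 1) / 2.0;
    double e = num / denom;
    out.push_back(e);
    if (e < cutoff) break;
  }
  return wrap(out);
}
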