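// Compiled core of the EHH/iHS scan: outward group-refinement walk from each
// core SNP with trapezoid integration of EHH over physical distance.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// One-sided iHH for one core/allele. reason: 0 ok, 1 too few carriers,
// 2 gap exceeded, 3 chromosome end before decay.
static double ihh_side(const IntegerMatrix& haps, const IntegerVector& pos,
                       int core, int allele, int dir, int lo, int hi,
                       double cutoff, double maxgap, int& reason) {
  const int nh = haps.nrow();
  std::vector<int> carriers;
  carriers.reserve(nh);
  for (int i = 0; i < nh; ++i) {
    int a = haps(i, core);
    if (a != NA_INTEGER && a == allele) carriers.push_back(i);
  }
  const int n = (int)carriers.size();
  if (n < 2) { reason = 1; return NA_REAL; }
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> ids(n, 0);
  double prev_pos = pos[core], prev_e = 1.0, ihh = 0.0;
  int k = core;
  while (true) {
    k += dir;
    if (k < lo || k > hi) { reason = 3; return NA_REAL; }
    double gap = std::fabs((double)pos[k] - prev_pos);
    if (gap > maxgap) { reason = 2; return NA_REAL; }
    std::unordered_map<long long, int> remap;
    remap.reserve(n * 2);
    int next_id = 0;
    std::vector<int> counts;
    counts.reserve(n);
    for (int c = 0; c < n; ++c) {
      int a = haps(carriers[c], k);
      int av = (a == NA_INTEGER) ? 2 : a;
      long long key = (long long)ids[c] * 3LL + av;
      auto it = remap.find(key);
      int nid;
      if (it == remap.end()) {
        nid = next_id++;
        remap.emplace(key, nid);
        counts.push_back(0);
      } else nid = it->second;
      ids[c] = nid;
      counts[nid]++;
    }
    double hom = 0.0;
    for (int g = 0; g < next_id; ++g)
      hom += (double)counts[g] * (counts[g] - 1) / 2.0;
    double e = hom / denom;
    ihh += 0.5 * (prev_e + e) * gap;
    prev_pos = pos[k];
    prev_e = e;
    if (e < cutoff) { reason = 0; return ihh; }
  }
}

// [[Rcpp::export(name = ".ihs_scan_chrom")]]
DataFrame ihs_scan_chrom(IntegerMatrix haps, IntegerVector pos,
                         LogicalVector derived_is_alt, NumericVector maf,
                         double maf_min, double cutoff, double maxgap) {
  const int m = pos.size();
  NumericVector ihh_a(m, NA_REAL), ihh_d(m, NA_REAL), unihs(m, NA_REAL);
  IntegerVector reason(m, 0);
  for (int j = 0; j < m; ++j) {
    if (NumericVector::is_na(maf[j]) || maf[j] < maf_min) {
      reason[j] = 4; // maf
      continue;
    }
    int derived = derived_is_alt[j] ? 1 : 0;
    int r = 0;
    double al = ihh_side(haps, pos, j, 1 - derived, -1, 0, m - 1, cutoff, maxgap, r);
    if (r) { reason[j] = r; continue; }
    double ar = ihh_side(haps, pos, j, 1 - derived, +1, 0, m - 1, cutoff, maxgap, r);
    if (r) { reason[j] = r; continue; }
    double dl = ihh_side(haps, pos, j, derived, -1, 0, m - 1, cutoff, maxgap, r);
    if (r) { reason[j] = r; continue; }
    double dr = ihh_side(haps, pos, j, derived, +1, 0, m - 1, cutoff, maxgap, r);
    if (r) { reason[j] = r; continue; }
    double ia = al + ar, id = dl + dr;
    ihh_a[j] = ia;
    ihh_d[j] = id;
    if (ia > 0 && id > 0) unihs[j] = std::log(ia / id);
    else reason[j] = 5; // zero ihh
  }
  return DataFrame::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                           _["unihs"] = unihs, _["reason"] = reason);
}
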