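#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Extended haplotype homozygosity decay from a core SNP, one direction.
// Identity is evaluated over the SNPs strictly beyond the core up to and
// including x, so EHH(core) == 1 by definition. Haplotype groups are
// refined incrementally; EHH(x) = sum_g C(n_g,2) / C(n,2).
static double side_area(const IntegerMatrix& haps, const NumericVector& pos,
                        int core, int dir, double cutoff,
                        std::vector<double>* curve_pos,
                        std::vector<double>* curve_ehh) {
  const int n = haps.ncol();
  const int m = haps.nrow();
  const double tot_pairs = n * (n - 1) / 2.0;
  if (tot_pairs <= 0) return NA_REAL;
  std::vector<int> grp(n, 0);
  int next_id = 1;
  double area = 0.0, prev_ehh = 1.0, prev_pos = pos[core];
  for (int i = core + dir; i >= 0 && i < m; i += dir) {
    std::map<std::pair<int, int>, int> remap;
    for (int j = 0; j < n; ++j) {
      std::pair<int, int> key(grp[j], haps(i, j));
      auto it = remap.find(key);
      if (it == remap.end()) {
        remap[key] = next_id;
        grp[j] = next_id++;
      } else {
        grp[j] = it->second;
      }
    }
    std::map<int, int> sizes;
    for (int j = 0; j < n; ++j) sizes[grp[j]]++;
    double pairs = 0.0;
    for (auto& kv : sizes) pairs += kv.second * (kv.second - 1) / 2.0;
    double ehh = pairs / tot_pairs;
    area += 0.5 * (prev_ehh + ehh) * std::abs(pos[i] - prev_pos);
    if (curve_pos) {
      curve_pos->push_back(pos[i]);
      curve_ehh->push_back(ehh);
    }
    if (ehh < cutoff) return area;
    prev_ehh = ehh;
    prev_pos = pos[i];
  }
  return area;
}

// [[Rcpp::export(name = ".ihh_core")]]
double ihh_core(IntegerMatrix haps, NumericVector pos, int core,
                double cutoff) {
  // core is 0-based here; R wrapper converts
  double l = side_area(haps, pos, core, -1, cutoff, nullptr, nullptr);
  double r = side_area(haps, pos, core, +1, cutoff, nullptr, nullptr);
  return l + r;
}

// [[Rcpp::export(name = ".ihh_all_cores")]]
NumericVector ihh_all_cores(IntegerMatrix haps, NumericVector pos,
                            double cutoff) {
  const int m = haps.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    out[i] = ihh_core(haps, pos, i, cutoff);
  }
  return out;
}

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
DataFrame ehh_curve_cpp(IntegerMatrix haps, NumericVector pos, int core) {
  std::vector<double> lp, le, rp, re;
  side_area(haps, pos, core, -1, -1.0, &lp, &le);  // cutoff -1: full flank
  side_area(haps, pos, core, +1, -1.0, &rp, &re);
  std::vector<double> allp, alle;
  std::vector<int> side;
  for (int i = (int)lp.size() - 1; i >= 0; --i) {
    allp.push_back(lp[i]); alle.push_back(le[i]); side.push_back(-1);
  }
  allp.push_back(pos[core]); alle.push_back(1.0); side.push_back(0);
  for (size_t i = 0; i < rp.size(); ++i) {
    allp.push_back(rp[i]); alle.push_back(re[i]); side.push_back(1);
  }
  return DataFrame::create(_["pos"] = allp, _["ehh"] = alle,
                           _["side"] = side);
}
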