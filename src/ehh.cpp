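// Extended-haplotype-homozygosity kernels.
//
// Haplotype matrices are sites x chromosomes, alleles coded 0/1,
// NA_INTEGER = missing. A chromosome with a missing call is removed from
// the extension from that marker outward (its pairs count as broken),
// which keeps profiles monotone non-increasing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static double homPairs(const std::vector<int>& grp) {
  std::unordered_map<int, int> cnt;
  for (int g : grp) cnt[g]++;
  double s = 0.0;
  for (const auto& kv : cnt) {
    s += (double)kv.second * (kv.second - 1) / 2.0;
  }
  return s;
}

// one extension step; returns false if no chromosome survives
static bool extendStep(const IntegerMatrix& hap, int marker,
                       std::vector<int>& members, std::vector<int>& grp) {
  std::unordered_map<long long, int> remap;
  std::vector<int> nm, ng;
  nm.reserve(members.size());
  ng.reserve(members.size());
  int nextId = 0;
  for (size_t i = 0; i < members.size(); ++i) {
    int a = hap(marker, members[i]);
    if (a == NA_INTEGER) continue;
    long long key = (long long)grp[i] * 2 + a;
    auto it = remap.find(key);
    int id;
    if (it == remap.end()) {
      id = nextId++;
      remap[key] = id;
    } else id = it->second;
    nm.push_back(members[i]);
    ng.push_back(id);
  }
  members.swap(nm);
  grp.swap(ng);
  return !members.empty();
}

// Walk from the core in one direction, returning marker indices (0-based)
// and homozygosity values hom/denom, truncated at the first marker where
// the value drops below `limit` (that marker included).
// [[Rcpp::export]]
List cpp_ehh_side(IntegerMatrix hap, int core0, IntegerVector members0,
                  IntegerVector initGrp, double denomPairs, int dir,
                  double limit) {
  std::vector<int> members(members0.begin(), members0.end());
  std::vector<int> grp(initGrp.begin(), initGrp.end());
  std::vector<int> outIdx;
  std::vector<double> outVal;
  int nSites = hap.nrow();
  int m = core0 + dir;
  while (m >= 0 && m < nSites) {
    if (!extendStep(hap, m, members, grp)) {
      outIdx.push_back(m);
      outVal.push_back(0.0);
      break;
    }
    double v = homPairs(grp) / denomPairs;
    outIdx.push_back(m);
    outVal.push_back(v);
    if (v < limit) break;
    m += dir;
  }
  return List::create(_["markers"] = wrap(outIdx),
                      _["values"] = wrap(outVal));
}

// Integrated EHHS (iES) for every site of one scaffold: trapezoidal
// integral over physical bp on each side, truncated at the first marker
// with EHHS < limit (included as boundary), sides summed. Sites whose
// EHHS is still >= limit when a scaffold border is reached are flagged
// unscorable (the border truncates the integral), as the field's scan
// tools do by default.
// [[Rcpp::export]]
List cpp_ies_scan(IntegerMatrix hap, IntegerVector positions,
                  double limit) {
  int nSites = hap.nrow(), nHap = hap.ncol();
  NumericVector ies(nSites, NA_REAL);
  LogicalVector scorable(nSites, false);
  for (int s = 0; s < nSites; ++s) {
    // core allele classes over non-missing chromosomes
    std::vector<int> members, grp;
    int n0 = 0, n1 = 0;
    for (int j = 0; j < nHap; ++j) {
      int a = hap(s, j);
      if (a == NA_INTEGER) continue;
      members.push_back(j);
      grp.push_back(a);
      if (a == 0) n0++; else n1++;
    }
    if (n0 == 0 || n1 == 0) continue;  // monomorphic core: unscorable
    double denom = (double)n0 * (n0 - 1) / 2.0 +
                   (double)n1 * (n1 - 1) / 2.0;
    if (denom <= 0) continue;
    bool anyFlank = (s > 0) || (s < nSites - 1);
    if (!anyFlank) { ies[s] = 0.0; continue; }
    double total = 0.0;
    bool borderTruncated = false;
    for (int dir = -1; dir <= 1; dir += 2) {
      std::vector<int> mem = members, g = grp;
      double prevVal = 1.0;
      double prevPos = (double)positions[s];
      int m = s + dir;
      bool decayed = false;
      while (m >= 0 && m < nSites) {
        double v;
        if (!extendStep(hap, m, mem, g)) v = 0.0;
        else v = homPairs(g) / denom;
        double pos = (double)positions[m];
        total += (prevVal + v) / 2.0 * std::abs(pos - prevPos);
        prevVal = v;
        prevPos = pos;
        if (v < limit) { decayed = true; break; }
        m += dir;
      }
      if (!decayed) borderTruncated = true;
    }
    if (borderTruncated) continue;  // NA, unscorable
    ies[s] = total;
    scorable[s] = true;
  }
  return List::create(_["ies"] = ies, _["scorable"] = scorable);
}
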