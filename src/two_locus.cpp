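// Two-locus coalescent simulation for composite-likelihood lookup tables.
//
// Simulates Hudson's two-locus ancestral process for n haploid samples at
// scaled recombination rho between the loci, then drops one mutation per
// locus uniformly by branch length (the small-theta limit of conditioning
// on both loci segregating) and records the resulting 2x2 haplotype
// configuration. Descendant sets are 128-bit masks, so n <= 128.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct Mask {
  uint64_t a, b;
  bool operator<(const Mask &o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
  bool operator==(const Mask &o) const { return a == o.a && b == o.b; }
  bool zero() const { return a == 0 && b == 0; }
  Mask orWith(const Mask &o) const { return Mask{a | o.a, b | o.b}; }
  Mask andWith(const Mask &o) const { return Mask{a & o.a, b & o.b}; }
  Mask andNot(const Mask &o) const { return Mask{a & ~o.a, b & ~o.b}; }
  int count() const {
    return __builtin_popcountll(a) + __builtin_popcountll(b);
  }
};

static Mask bitMask(int i) {
  if (i < 64) return Mask{uint64_t(1) << i, 0};
  return Mask{0, uint64_t(1) << (i - 64)};
}

struct Lineage {
  Mask A, B; // descendant sets at each locus; zero = not ancestral there
};

// draw a mask proportional to accumulated branch length
static Mask drawMask(const std::vector<Mask> &keys,
                     const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  size_t lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return keys[lo];
}

// [[Rcpp::export(name = ".twoLocusConfigs")]]
IntegerMatrix twoLocusConfigs(int n, double rho, int nSims, int mutDraws) {
  if (n < 2 || n > 128) stop("sample size must be in [2, 128]");
  if (nSims < 1 || mutDraws < 1) stop("nSims and mutDraws must be positive");
  Mask full{0, 0};
  for (int i = 0; i < n; ++i) full = full.orWith(bitMask(i));

  IntegerMatrix out(nSims * mutDraws, 4);
  std::vector<Lineage> lin;
  std::map<Mask, double> wA, wB;

  for (int s = 0; s < nSims; ++s) {
    lin.clear();
    wA.clear();
    wB.clear();
    for (int i = 0; i < n; ++i) lin.push_back(Lineage{bitMask(i), bitMask(i)});

    int guard = 0;
    while (!lin.empty()) {
      if (++guard > 100000000) stop("two-locus simulation failed to coalesce");
      int k = (int)lin.size();
      int nab = 0;
      for (const Lineage &l : lin)
        if (!l.A.zero() && !l.B.zero()) ++nab;
      double rateC = 0.5 * k * (k - 1);
      double rateR = 0.5 * rho * nab;
      double tot = rateC + rateR;
      double dt = exp_rand() / tot;
      for (const Lineage &l : lin) {
        if (!l.A.zero()) wA[l.A] += dt;
        if (!l.B.zero()) wB[l.B] += dt;
      }
      if (unif_rand() * tot < rateC) {
        int i = (int)(unif_rand() * k);
        int j = (int)(unif_rand() * (k - 1));
        if (j >= i) ++j;
        Mask nA = lin[i].A.orWith(lin[j].A);
        Mask nB = lin[i].B.orWith(lin[j].B);
        if (nA == full) nA = Mask{0, 0}; // locus A reached its MRCA
        if (nB == full) nB = Mask{0, 0};
        lin[i] = Lineage{nA, nB};
        lin.erase(lin.begin() + j);
        if (i > j) --i;
        if (lin[i].A.zero() && lin[i].B.zero()) lin.erase(lin.begin() + i);
      } else {
        int pick = (int)(unif_rand() * nab);
        for (size_t i = 0; i < lin.size(); ++i) {
          if (!lin[i].A.zero() && !lin[i].B.zero()) {
            if (pick-- == 0) {
              Mask B = lin[i].B;
              lin[i].B = Mask{0, 0};
              lin.push_back(Lineage{Mask{0, 0}, B});
              break;
            }
          }
        }
      }
    }

    // cumulative weights for conditional mutation placement
    std::vector<Mask> keysA, keysB;
    std::vector<double> cumA, cumB;
    double accA = 0, accB = 0;
    for (auto &kv : wA) { keysA.push_back(kv.first); accA += kv.second; cumA.push_back(accA); }
    for (auto &kv : wB) { keysB.push_back(kv.first); accB += kv.second; cumB.push_back(accB); }
    if (keysA.empty() || keysB.empty()) stop("degenerate genealogy: no branches");

    for (int d = 0; d < mutDraws; ++d) {
      Mask mA = drawMask(keysA, cumA);
      Mask mB = drawMask(keysB, cumB);
      int n11 = mA.andWith(mB).count();
      int n10 = mA.andNot(mB).count();
      int n01 = mB.andNot(mA).count();
      int row = s * mutDraws + d;
      out(row, 0) = n11;
      out(row, 1) = n10;
      out(row, 2) = n01;
      out(row, 3) = n - n11 - n10 - n01;
    }
  }
  return out;
}
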