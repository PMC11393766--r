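// Backward-in-time structured coalescent engine.
//
// Model conventions (shared with the R layer):
//  * time runs backward from the present, in generations;
//  * demes are diploid populations of effective size N (so a pair of haploid
//    lineages in a deme coalesces at rate 1/(2N) per generation);
//  * divergence events move every lineage of `src` into `snk` and retire
//    `src`; size-change events reset N looking further backward;
//  * migration is documented forward in time: rates(i, j) is the fraction of
//    deme j founded each generation by migrants from deme i.  Backward in
//    time that same number is the probability that a lineage currently in j
//    had its parent in i, so a lineage in deme j jumps to deme i at rate
//    rates(i, j), and only while t < mig_end (recent migration only).
//
// Mutation is infinite-sites with opportunity theta = mu * locus_length per
// generation per lineage; conditional on a genealogy of total length T the
// locus is monomorphic with probability exp(-theta * T) and otherwise the
// first (retained) mutation falls on a branch with probability proportional
// to its length.  The expected-SFS estimator is Rao-Blackwellized over
// mutation placement: each genealogy contributes exp(-theta T) to the
// monomorphic cell and (1 - exp(-theta T)) * L_c / T to cell c, where L_c is
// the branch length subtending configuration c.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>

using namespace Rcpp;

namespace {

const int MAXPOP = 8;
const int MAXW = 4; // up to 256 sampled haplotypes

struct Branch {
  double len;
  int cnt[MAXPOP];         // sampled descendants per deme
  uint64_t mask[MAXW];     // descendant tip set (only if tracked)
};

struct ModelC {
  int npop;
  double N0[MAXPOP];               // present-day diploid sizes
  std::vector<double> evTime;      // sorted ascending
  std::vector<int> evKind;         // 0 divergence, 1 size change
  std::vector<int> evA;            // divergence src / size-change deme
  std::vector<int> evB;            // divergence snk (unused for size change)
  std::vector<double> evSize;      // size-change new size
  double mig[MAXPOP * MAXPOP];     // mig[i + MAXPOP*j]: lineage in j -> i
  double migEnd;
  bool hasMig;
};

ModelC unpackModel(const List& model) {
  ModelC m;
  NumericVector N = model["N"];
  m.npop = N.size();
  if (m.npop > MAXPOP) stop("at most %d demes supported", MAXPOP);
  for (int d = 0; d < m.npop; ++d) m.N0[d] = N[d];
  NumericVector evTime = model["evTime"];
  IntegerVector evKind = model["evKind"], evA = model["evA"], evB = model["evB"];
  NumericVector evSize = model["evSize"];
  m.evTime.assign(evTime.begin(), evTime.end());
  m.evKind.assign(evKind.begin(), evKind.end());
  m.evA.assign(evA.begin(), evA.end());
  m.evB.assign(evB.begin(), evB.end());
  m.evSize.assign(evSize.begin(), evSize.end());
  for (size_t e = 1; e < m.evTime.size(); ++e)
    if (m.evTime[e] < m.evTime[e - 1]) stop("events must be sorted by time");
  m.hasMig = false;
  m.migEnd = 0.0;
  std::memset(m.mig, 0, sizeof(m.mig));
  if (model.containsElementNamed("mig") && !Rf_isNull(model["mig"])) {
    NumericMatrix mg = model["mig"];
    if (mg.nrow() != m.npop || mg.ncol() != m.npop)
      stop("migration matrix dimension mismatch");
    for (int i = 0; i < m.npop; ++i)
      for (int j = 0; j < m.npop; ++j) {
        m.mig[i + MAXPOP * j] = mg(i, j);
        if (mg(i, j) > 0.0) m.hasMig = true;
      }
    m.migEnd = as<double>(model["migEnd"]);
    if (m.migEnd <= 0.0) m.hasMig = false;
  }
  return m;
}

// Reusable simulation state: one genealogy at a time, no per-run allocation.
struct Sim {
  const ModelC& m;
  int nTot;
  int sampleN[MAXPOP];
  bool needMask;
  // lineage storage (index = slot)
  std::vector<int> deme;
  std::vector<double> birth;
  std::vector<int> cnt;                 // nTot slots x MAXPOP
  std::vector<uint64_t> mask;           // nTot slots x MAXW
  std::vector<int> byDeme[MAXPOP];
  std::vector<int> pos;
  std::vector<Branch> branches;
  double totLen;

  Sim(const ModelC& model, const int* sn, bool mask_) : m(model), needMask(mask_) {
    nTot = 0;
    for (int d = 0; d < m.npop; ++d) { sampleN[d] = sn[d]; nTot += sn[d]; }
    if (nTot < 1) stop("no sampled lineages");
    if (nTot > 64 * MAXW) stop("too many sampled haplotypes");
    deme.resize(nTot);
    birth.resize(nTot);
    cnt.resize((size_t)nTot * MAXPOP);
    mask.resize((size_t)nTot * MAXW);
    pos.resize(nTot);
    for (int d = 0; d < m.npop; ++d) byDeme[d].reserve(nTot);
    branches.reserve(2 * nTot);
  }

  inline int* cntOf(int lid) { return &cnt[(size_t)lid * MAXPOP]; }
  inline uint64_t* maskOf(int lid) { return &mask[(size_t)lid * MAXW]; }

  inline void removeFromDeme(int lid) {
    std::vector<int>& v = byDeme[deme[lid]];
    int p = pos[lid], last = v.back();
    v[p] = last;
    pos[last] = p;
    v.pop_back();
  }
  inline void addToDeme(int lid, int d) {
    deme[lid] = d;
    pos[lid] = (int)byDeme[d].size();
    byDeme[d].push_back(lid);
  }
  inline void recordBranch(double t, int lid) {
    Branch br;
    br.len = t - birth[lid];
    std::memcpy(br.cnt, cntOf(lid), sizeof(br.cnt));
    if (needMask) std::memcpy(br.mask, maskOf(lid), sizeof(br.mask));
    totLen += br.len;
    branches.push_back(br);
  }

  // simulate one genealogy; returns total tree length
  double run() {
    const int npop = m.npop;
    for (int d = 0; d < npop; ++d) byDeme[d].clear();
    branches.clear();
    totLen = 0.0;
    int id = 0;
    for (int d = 0; d < npop; ++d)
      for (int s = 0; s < sampleN[d]; ++s, ++id) {
        birth[id] = 0.0;
        int* c = cntOf(id);
        std::memset(c, 0, sizeof(int) * MAXPOP);
        c[d] = 1;
        if (needMask) {
          uint64_t* w = maskOf(id);
          std::memset(w, 0, sizeof(uint64_t) * MAXW);
          w[id >> 6] = (uint64_t)1 << (id & 63);
        }
        addToDeme(id, d);
      }

    double N[MAXPOP];
    bool active[MAXPOP];
    double outRate[MAXPOP];
    for (int d = 0; d < npop; ++d) { N[d] = m.N0[d]; active[d] = true; }
    bool migOn = m.hasMig;
    auto recomputeOut = [&]() {
      for (int j = 0; j < npop; ++j) {
        double s = 0.0;
        for (int i = 0; i < npop; ++i)
          if (active[i] && i != j) s += m.mig[i + MAXPOP * j];
        outRate[j] = s;
      }
    };
    if (migOn) recomputeOut();

    double t = 0.0;
    size_t evPtr = 0;
    int nAlive = nTot;

    while (nAlive > 1) {
      double tb = R_PosInf;
      bool bndIsEvent = false;
      if (evPtr < m.evTime.size()) { tb = m.evTime[evPtr]; bndIsEvent = true; }
      if (migOn && m.migEnd < tb) { tb = m.migEnd; bndIsEvent = false; }

      double coalTot = 0.0, migTot = 0.0;
      double coalD[MAXPOP];
      for (int d = 0; d < npop; ++d) {
        double k = (double)byDeme[d].size();
        coalD[d] = (k >= 2.0) ? k * (k - 1.0) / (4.0 * N[d]) : 0.0;
        coalTot += coalD[d];
        if (migOn && k > 0.0) migTot += k * outRate[d];
      }
      double R = coalTot + migTot;

      double dt = (R > 0.0) ? R::exp_rand() / R : R_PosInf;
      if (t + dt >= tb) {
        if (!R_FINITE(tb))
          stop("invalid model: lineages can never fully coalesce");
        t = tb;
        if (!bndIsEvent) { migOn = false; continue; }
        while (evPtr < m.evTime.size() && m.evTime[evPtr] <= t) {
          int k = m.evKind[evPtr], a = m.evA[evPtr];
          if (k == 0) {
            int b = m.evB[evPtr];
            if (!active[a] || !active[b])
              stop("invalid model: divergence references a retired deme");
            // move all lineages of a into b
            for (int lid : std::vector<int>(byDeme[a])) {
              removeFromDeme(lid);
              addToDeme(lid, b);
            }
            active[a] = false;
            if (migOn) recomputeOut();
          } else {
            N[a] = m.evSize[evPtr];
          }
          ++evPtr;
        }
        if (migOn && t >= m.migEnd) migOn = false;
        continue;
      }

      t += dt;
      double u = unif_rand() * R;
      if (u < coalTot) {
        int d = 0;
        double c = coalD[0];
        while (u >= c && d + 1 < npop) { ++d; c += coalD[d]; }
        std::vector<int>& v = byDeme[d];
        int k = (int)v.size();
        int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
        int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
        if (i2 >= i1) ++i2;
        int a = v[i1], b = v[i2];
        recordBranch(t, a);
        recordBranch(t, b);
        int* ca = cntOf(a);
        const int* cb = cntOf(b);
        for (int p = 0; p < npop; ++p) ca[p] += cb[p];
        if (needMask) {
          uint64_t* wa = maskOf(a);
          const uint64_t* wb = maskOf(b);
          for (int w = 0; w < MAXW; ++w) wa[w] |= wb[w];
        }
        birth[a] = t;
        removeFromDeme(b);
        --nAlive;
      } else {
        u -= coalTot;
        int j = 0;
        double c = (double)byDeme[0].size() * outRate[0];
        while (u >= c && j + 1 < npop) {
          ++j;
          c += (double)byDeme[j].size() * outRate[j];
        }
        int k = (int)byDeme[j].size();
        if (k == 0 || outRate[j] <= 0.0) continue; // numerical edge; resample
        int li = (int)(unif_rand() * k); if (li >= k) li = k - 1;
        int lid = byDeme[j][li];
        double u2 = unif_rand() * outRate[j];
        int dest = -1;
        double cc = 0.0;
        for (int i = 0; i < npop; ++i) {
          if (!active[i] || i == j) continue;
          cc += m.mig[i + MAXPOP * j];
          if (u2 < cc) { dest = i; break; }
        }
        if (dest < 0) continue;
        removeFromDeme(lid);
        addToDeme(lid, dest);
      }
    }
    return totLen;
  }
};

} // namespace

//' @keywords internal
// [[Rcpp::export(name = ".cpp_expected_sfs")]]
List cpp_expected_sfs(List model, IntegerVector sampleN, int nSims, double theta,
                      IntegerMatrix pairIdx) {
  ModelC m = unpackModel(model);
  if ((int)sampleN.size() != m.npop) stop("sampleN length must equal number of demes");
  int sn[MAXPOP];
  for (int d = 0; d < m.npop; ++d) sn[d] = sampleN[d];
  if (nSims < 1) stop("nSims must be >= 1");
  if (theta <= 0) stop("theta must be > 0");
  const int npair = pairIdx.ncol();
  std::vector<NumericMatrix> accM;
  std::vector<double*> acc(npair);
  std::vector<int> pa(npair), pb(npair), na(npair), nb(npair), nrow(npair);
  for (int p = 0; p < npair; ++p) {
    pa[p] = pairIdx(0, p);
    pb[p] = pairIdx(1, p); // -1 => 1D spectrum for deme pa
    if (pa[p] < 0 || pa[p] >= m.npop || pb[p] >= m.npop)
      stop("pair index out of range");
    na[p] = sn[pa[p]];
    nb[p] = (pb[p] >= 0) ? sn[pb[p]] : 0;
    nrow[p] = na[p] + 1;
    accM.push_back(NumericMatrix(nrow[p], nb[p] + 1));
    acc[p] = accM[p].begin();
  }

  RNGScope scope;
  Sim sim(m, sn, false);
  for (int s = 0; s < nSims; ++s) {
    double T = sim.run();
    double pNo = std::exp(-theta * T);
    double w = (T > 0.0) ? (1.0 - pNo) / T : 0.0;
    size_t nbr = sim.branches.size();
    for (int p = 0; p < npair; ++p) {
      const int A = pa[p], B = pb[p], nA = na[p], nB = nb[p], nr = nrow[p];
      double* out = acc[p];
      double seen = 0.0; // branch length landing in cells other than (0,0)
      if (B >= 0) {
        const int tot = nA + nB;
        for (size_t q = 0; q < nbr; ++q) {
          const Branch& br = sim.branches[q];
          int i = br.cnt[A], j = br.cnt[B];
          if (i == 0 && j == 0) continue;
          if (2 * (i + j) > tot) { i = nA - i; j = nB - j; }
          if (i == 0 && j == 0) continue; // branch above the whole pair sample
          out[i + nr * j] += w * br.len;
          seen += br.len;
        }
      } else {
        for (size_t q = 0; q < nbr; ++q) {
          const Branch& br = sim.branches[q];
          int i = br.cnt[A];
          if (i == 0) continue;
          if (2 * i > nA) i = nA - i;
          if (i == 0) continue;
          out[i] += w * br.len;
          seen += br.len;
        }
      }
      // monomorphic-for-the-pair cell: no mutation, a mutation on a branch
      // with no sampled descendants in the pair, or one above all of them
      out[0] += pNo + w * (T - seen);
    }
  }
  List out(npair);
  for (int p = 0; p < npair; ++p) {
    NumericMatrix a = accM[p];
    for (int i = 0; i < a.size(); ++i) a[i] /= (double)nSims;
    out[p] = a;
  }
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".cpp_simulate_haplotypes")]]
List cpp_simulate_haplotypes(List model, IntegerVector sampleN, int nLoci,
                             double theta, bool oneSnpPerLocus) {
  ModelC m = unpackModel(model);
  if ((int)sampleN.size() != m.npop) stop("sampleN length must equal number of demes");
  int sn[MAXPOP];
  int nTot = 0;
  for (int d = 0; d < m.npop; ++d) { sn[d] = sampleN[d]; nTot += sn[d]; }
  if (nTot < 1) stop("model has zero sampled haplotypes");
  if (nLoci < 1) stop("nLoci must be >= 1");

  RNGScope scope;
  Sim sim(m, sn, true);
  std::vector<uint8_t> rows;       // flattened site x haplotype
  std::vector<int> locusOf;
  std::vector<int> isVar;
  rows.reserve((size_t)nLoci * nTot);

  auto emitZero = [&](int locus) {
    rows.insert(rows.end(), nTot, (uint8_t)0);
    locusOf.push_back(locus);
    isVar.push_back(0);
  };
  auto emitBranch = [&](int locus, double T) {
    double r = unif_rand() * T, cum = 0.0;
    const Branch* hit = &sim.branches.back();
    for (const Branch& br : sim.branches) {
      cum += br.len;
      if (r <= cum) { hit = &br; break; }
    }
    size_t base = rows.size();
    rows.insert(rows.end(), nTot, (uint8_t)0);
    for (int h = 0; h < nTot; ++h)
      if (hit->mask[h >> 6] & ((uint64_t)1 << (h & 63))) rows[base + h] = 1;
    locusOf.push_back(locus);
    isVar.push_back(1);
  };

  for (int l = 0; l < nLoci; ++l) {
    double T = sim.run();
    if (oneSnpPerLocus) {
      if (unif_rand() < std::exp(-theta * T)) emitZero(l + 1);
      else emitBranch(l + 1, T);
    } else {
      int nmut = (int)R::rpois(theta * T);
      if (nmut == 0) emitZero(l + 1);
      else for (int mu = 0; mu < nmut; ++mu) emitBranch(l + 1, T);
    }
  }

  int nSites = (int)locusOf.size();
  IntegerMatrix H(nSites, nTot);
  for (int i = 0; i < nSites; ++i)
    for (int h = 0; h < nTot; ++h) H(i, h) = rows[(size_t)i * nTot + h];
  return List::create(_["haplotypes"] = H,
                      _["locus"] = wrap(locusOf),
                      _["is_variable"] = wrap(isVar));
}
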