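// Wright-Fisher forward simulator with overdominance.
//
// Haplotypes are bit rows over a registry of mutation slots: slot k holds
// the (continuous, infinite-sites) position of one segregating mutation and
// bit k of a haplotype says whether it carries it.  A gamete is then a
// word-level copy of a parent row, a recombinant gamete an (a & mask) |
// (b & ~mask) with a per-crossover position mask, and new mutations are
// Poisson(mu*L) bit sets in freshly allocated slots.  Slots of lost
// mutations are recycled and fixed mutations are moved to a per-population
// fixed list when free slots run low, so rows stay a handful of words wide
// regardless of how long the simulation runs.
//
// The balanced variant sits at exactly L/2 in its own slot; parents are
// drawn by fitness-weighted rejection sampling once it segregates, and the
// run is conditioned on its maintenance by restoring a snapshot taken at
// the introduction generation whenever it is lost (or, degenerately, fixes
// and the polymorphism is gone).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>
#include <cmath>

namespace {

// xoshiro256++ seeded via splitmix64: fast, and independent of R's RNG so
// a SimConfig seed reproduces bit-identically.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

// Knuth's multiplicative Poisson; mu*L is tiny here.
inline int rpoisSmall(RNG& rng, double expNegMu) {
  int k = 0;
  double p = 1.0;
  for (;;) {
    p *= rng.u01();
    if (p <= expNegMu) return k;
    ++k;
  }
}

struct Population {
  int twoN = 0;
  int words = 0;                    // 64-bit words per haplotype row
  std::vector<uint64_t> cur, nxt;   // twoN * words each
  std::vector<double> pos;          // slot -> mutation position
  std::vector<uint8_t> used;        // slot occupied
  std::vector<int> freeSlots;
  std::vector<double> fixed;        // fixed in this population

  void init(int twoN_, int words_) {
    twoN = twoN_;
    words = words_;
    cur.assign((size_t)twoN * words, 0);
    nxt.assign((size_t)twoN * words, 0);
    pos.assign((size_t)words * 64, 0.0);
    used.assign((size_t)words * 64, 0);
    freeSlots.clear();
    for (int k = words * 64 - 1; k >= 0; --k) freeSlots.push_back(k);
    fixed.clear();
  }
  inline uint64_t* row(std::vector<uint64_t>& b, int h) {
    return b.data() + (size_t)h * words;
  }
  inline const uint64_t* crow(const std::vector<uint64_t>& b, int h) const {
    return b.data() + (size_t)h * words;
  }
  inline bool testBit(const uint64_t* r, int slot) const {
    return (r[slot >> 6] >> (slot & 63)) & 1ULL;
  }
  inline void setBit(uint64_t* r, int slot) {
    r[slot >> 6] |= 1ULL << (slot & 63);
  }
  int alloc(double position) {
    int slot = freeSlots.back();
    freeSlots.pop_back();
    pos[slot] = position;
    used[slot] = 1;
    return slot;
  }

  // Recycle lost slots, move fixed mutations to the fixed list.
  void cleanup(int balSlot) {
    int nSlots = words * 64;
    std::vector<int> cnt(nSlots, 0);
    for (int h = 0; h < twoN; ++h) {
      const uint64_t* r = crow(cur, h);
      for (int w = 0; w < words; ++w) {
        uint64_t word = r[w];
        while (word) {
          cnt[w * 64 + __builtin_ctzll(word)]++;
          word &= word - 1;
        }
      }
    }
    for (int k = 0; k < nSlots; ++k) {
      if (!used[k] || k == balSlot) continue;
      if (cnt[k] == 0) {
        used[k] = 0;
        freeSlots.push_back(k);
      } else if (cnt[k] == twoN) {
        fixed.push_back(pos[k]);
        uint64_t mask = ~(1ULL << (k & 63));
        int w = k >> 6;
        for (int h = 0; h < twoN; ++h) row(cur, h)[w] &= mask;
        used[k] = 0;
        freeSlots.push_back(k);
      }
    }
  }

  // Widen rows by one word (64 new slots).
  void grow() {
    int nw = words + 1;
    std::vector<uint64_t> nb((size_t)twoN * nw, 0);
    for (int h = 0; h < twoN; ++h)
      std::memcpy(nb.data() + (size_t)h * nw, crow(cur, h),
                  (size_t)words * 8);
    cur.swap(nb);
    nxt.assign((size_t)twoN * nw, 0);
    pos.resize((size_t)nw * 64, 0.0);
    used.resize((size_t)nw * 64, 0);
    for (int k = nw * 64 - 1; k >= words * 64; --k) freeSlots.push_back(k);
    words = nw;
  }
  void ensureCapacity(int margin, int balSlot) {
    if ((int)freeSlots.size() >= margin) return;
    cleanup(balSlot);
    while ((int)freeSlots.size() < margin) grow();
  }
};

struct Snapshot {
  int words;
  std::vector<uint64_t> bits;
  std::vector<double> pos;
  std::vector<uint8_t> used;
  std::vector<int> freeSlots;
  std::vector<double> fixed;
};

void takeSnapshot(const Population& p, Snapshot& s) {
  s.words = p.words;
  s.bits = p.cur;
  s.pos = p.pos;
  s.used = p.used;
  s.freeSlots = p.freeSlots;
  s.fixed = p.fixed;
}

void restoreSnapshot(Population& p, const Snapshot& s) {
  p.words = s.words;
  p.cur = s.bits;
  p.nxt.assign(p.cur.size(), 0);
  p.pos = s.pos;
  p.used = s.used;
  p.freeSlots = s.freeSlots;
  p.fixed = s.fixed;
}

struct Params {
  double L, rL, expNegMuL;
  double wHet, wHom;
  int margin;
};

// One generation cur -> nxt; returns the gamete count of balSlot (only
// meaningful under selection).
int nextGen(Population& p, RNG& rng, const Params& par, bool sel, int balSlot,
            std::vector<uint64_t>& maskBuf, std::vector<double>& wBuf) {
  const int twoN = p.twoN, N = twoN / 2, words = p.words;
  double wMax = 1.0;
  if (sel) {
    wBuf.resize(N);
    for (int i = 0; i < N; ++i) {
      int g = (p.testBit(p.crow(p.cur, 2 * i), balSlot) ? 1 : 0) +
              (p.testBit(p.crow(p.cur, 2 * i + 1), balSlot) ? 1 : 0);
      wBuf[i] = (g == 0) ? 1.0 : (g == 1 ? par.wHet : par.wHom);
    }
    wMax = std::max(1.0, std::max(par.wHet, par.wHom));
  }
  int balCount = 0;
  for (int j = 0; j < twoN; ++j) {
    int parent;
    if (sel) {
      for (;;) {  // fitness-weighted rejection sampling
        parent = (int)(rng.u01() * N);
        if (parent >= N) parent = N - 1;
        if (rng.u01() * wMax <= wBuf[parent]) break;
      }
    } else {
      parent = (int)(rng.u01() * N);
      if (parent >= N) parent = N - 1;
    }
    int coin = (int)(rng.next() & 1ULL);
    const uint64_t* a = p.crow(p.cur, 2 * parent + coin);
    uint64_t* dst = p.row(p.nxt, j);
    if (rng.u01() < par.rL) {
      const uint64_t* b = p.crow(p.cur, 2 * parent + (coin ^ 1));
      double x = rng.u01() * par.L;
      maskBuf.resize(words);
      for (int w = 0; w < words; ++w) {
        uint64_t m = 0;
        for (int bi = 0; bi < 64; ++bi)
          if (p.pos[w * 64 + bi] < x) m |= 1ULL << bi;
        maskBuf[w] = m;
      }
      for (int w = 0; w < words; ++w)
        dst[w] = (a[w] & maskBuf[w]) | (b[w] & ~maskBuf[w]);
    } else {
      std::memcpy(dst, a, (size_t)words * 8);
    }
    int nm = rpoisSmall(rng, par.expNegMuL);
    for (int k = 0; k < nm; ++k)
      p.setBit(dst, p.alloc(rng.u01() * par.L));
    if (sel && p.testBit(dst, balSlot)) ++balCount;
  }
  p.cur.swap(p.nxt);
  return balCount;
}

void evolveNeutral(Population& p, RNG& rng, const Params& par, long gens,
                   std::vector<uint64_t>& maskBuf, std::vector<double>& wBuf) {
  for (long g = 0; g < gens; ++g) {
    p.ensureCapacity(par.margin, -1);
    nextGen(p, rng, par, false, -1, maskBuf, wBuf);
    if ((g & 1023) == 0) Rcpp::checkUserInterrupt();
  }
}

} // namespace

// [[Rcpp::export(name = ".cppRunForward")]]
Rcpp::List cppRunForward(int Ne, double mu, double r, double L, double burnIn,
                         double splitGens, double tSel, double h, double s,
                         int nSample, bool balanced, bool outgroup,
                         double maxRestarts, double seed) {
  const int twoN = 2 * Ne;
  const double muL = mu * L;
  const double balPos = L / 2.0;
  Params par;
  par.L = L;
  par.rL = r * L;
  par.expNegMuL = std::exp(-muL);
  par.wHet = 1.0 + h * s;
  par.wHom = 1.0 + s;
  par.margin = std::max(64, (int)(6 * twoN * muL));
  if (balanced && (par.wHet <= 0 || par.wHom <= 0))
    Rcpp::stop("fitnesses must be positive (check h and s after rescaling)");

  RNG rng((uint64_t)seed);
  std::vector<uint64_t> maskBuf;
  std::vector<double> wBuf;

  // Initial row width sized for the expected segregating load.
  double thetaPop = 2.0 * twoN * muL;
  int slots0 = (int)(2 * thetaPop * (std::log(twoN) + 0.577)) + 2 * par.margin;
  Population human;
  human.init(twoN, std::max(2, (slots0 + 63) / 64));

  evolveNeutral(human, rng, par, (long)burnIn, maskBuf, wBuf);
  human.cleanup(-1);

  Population chimp;
  if (outgroup) {
    chimp = human;  // species split
    evolveNeutral(chimp, rng, par, (long)splitGens, maskBuf, wBuf);
    chimp.cleanup(-1);
  }

  const long introGen = (long)splitGens - (long)tSel;
  long restarts = 0;
  bool introduced = false;
  int balSlot = -1;
  Snapshot snap;
  long g = 0;
  while (g < (long)splitGens) {
    if (balanced && !introduced && g == introGen) {
      human.cleanup(-1);
      human.ensureCapacity(par.margin, -1);
      balSlot = human.alloc(balPos);
      int target = (int)(rng.u01() * twoN);
      if (target >= twoN) target = twoN - 1;
      human.setBit(human.row(human.cur, target), balSlot);
      takeSnapshot(human, snap);
      introduced = true;
    }
    bool sel = balanced && introduced;
    human.ensureCapacity(par.margin, sel ? balSlot : -1);
    int balCount = nextGen(human, rng, par, sel, balSlot, maskBuf, wBuf);
    ++g;
    if (sel && (balCount == 0 || balCount == twoN)) {
      ++restarts;
      if (restarts > (long)maxRestarts)
        Rcpp::stop("restart budget (%g) exceeded: balanced variant with h=%g, "
                   "s=%g could not be maintained", maxRestarts, h, s);
      restoreSnapshot(human, snap);
      g = introGen;
      continue;
    }
    if ((g & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  human.cleanup(balanced ? balSlot : -1);

  // Sample nSample focal chromosomes without replacement.
  std::vector<int> idx(twoN);
  for (int i = 0; i < twoN; ++i) idx[i] = i;
  for (int i = 0; i < nSample; ++i) {
    int j = i + (int)(rng.u01() * (twoN - i));
    if (j >= twoN) j = twoN - 1;
    std::swap(idx[i], idx[j]);
  }
  int nSlots = human.words * 64;
  std::vector<int> cnt(nSlots, 0);
  for (int i = 0; i < nSample; ++i) {
    const uint64_t* row = human.crow(human.cur, idx[i]);
    for (int w = 0; w < human.words; ++w) {
      uint64_t word = row[w];
      while (word) {
        cnt[w * 64 + __builtin_ctzll(word)]++;
        word &= word - 1;
      }
    }
  }
  std::vector<double> segPos, fixedInSample;
  std::vector<int> segCount;
  int balSampleCount = 0;
  for (int k = 0; k < nSlots; ++k) {
    if (!human.used[k] || cnt[k] == 0) continue;
    if (k == balSlot) balSampleCount = cnt[k];
    if (cnt[k] <= nSample - 1) {
      segPos.push_back(human.pos[k]);
      segCount.push_back(cnt[k]);
    } else {
      fixedInSample.push_back(human.pos[k]);
    }
  }
  {  // sort sites by position
    std::vector<int> ord(segPos.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return segPos[a] < segPos[b]; });
    std::vector<double> sp(segPos.size());
    std::vector<int> sc(segPos.size());
    for (size_t i = 0; i < ord.size(); ++i) {
      sp[i] = segPos[ord[i]];
      sc[i] = segCount[ord[i]];
    }
    segPos.swap(sp);
    segCount.swap(sc);
  }

  std::vector<double> humanFixedAll(fixedInSample);
  humanFixedAll.insert(humanFixedAll.end(), human.fixed.begin(),
                       human.fixed.end());
  std::sort(humanFixedAll.begin(), humanFixedAll.end());

  // Substitutions: variants where the single outgroup chromosome's allele
  // is not present among the sampled focal chromosomes.
  std::vector<double> subs;
  if (outgroup) {
    int cIdx = (int)(rng.u01() * twoN);
    if (cIdx >= twoN) cIdx = twoN - 1;
    std::vector<double> chimpSet;
    const uint64_t* row = chimp.crow(chimp.cur, cIdx);
    for (int w = 0; w < chimp.words; ++w) {
      uint64_t word = row[w];
      while (word) {
        chimpSet.push_back(chimp.pos[w * 64 + __builtin_ctzll(word)]);
        word &= word - 1;
      }
    }
    chimpSet.insert(chimpSet.end(), chimp.fixed.begin(), chimp.fixed.end());
    std::sort(chimpSet.begin(), chimpSet.end());
    for (double q : humanFixedAll)
      if (!std::binary_search(chimpSet.begin(), chimpSet.end(), q))
        subs.push_back(q);
    for (double q : chimpSet)
      if (!std::binary_search(humanFixedAll.begin(), humanFixedAll.end(), q) &&
          !std::binary_search(segPos.begin(), segPos.end(), q))
        subs.push_back(q);
    std::sort(subs.begin(), subs.end());
  }

  return Rcpp::List::create(
      Rcpp::Named("positions") = Rcpp::wrap(segPos),
      Rcpp::Named("counts") = Rcpp::wrap(segCount),
      Rcpp::Named("substitutions") = Rcpp::wrap(subs),
      Rcpp::Named("balancedPos") = balPos,
      Rcpp::Named("balancedCount") = balSampleCount,
      Rcpp::Named("restarts") = (double)restarts);
}
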